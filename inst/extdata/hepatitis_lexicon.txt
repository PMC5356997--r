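# hepatitis-A worked-example lexicon (pinyin transcription)
JIA XING
BING DU XING GAN YAN
GAN HUN MI
JI XING
ZHONG XING
YA JI XING
JIA GAN
BU BAN
BAN
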