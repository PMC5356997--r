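JIA XING BING DU XING GAN YAN BAN GAN HUN MI	B15.000
JI XING JIA XING BING DU XING GAN YAN BAN GAN HUN MI	B15.001
JI XING ZHONG XING JIA XING BING DU XING GAN YAN BAN GAN HUN MI	B15.002
YA JI XING ZHONG XING JIA XING BING DU XING GAN YAN BAN GAN HUN MI	B15.003
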