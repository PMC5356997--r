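abbrev-hepatitis-a-1	0.9	JIA GAN|JIA XING
abbrev-hepatitis-a-2	0.9	JIA GAN|BING DU XING GAN YAN
serum-hepatitis	0.9	YI XING GAN YAN|XUE QING XING GAN YAN
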