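>MBP_E374_tail
SGSEYS
>MBP_D374_tail
SGSDYS
>MBP_K374_tail
SGSKYS
>MBP_S374_tail
SGSSYS
>hTG_siteA_flank
NIFEY
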