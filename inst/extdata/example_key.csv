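item_id,truth,gap_category
item01,same,0-2y
item02,same,0-2y
item03,same,2-8y
item04,same,2-8y
item05,same,2-8y
item06,same,2-8y
item07,same,2-8y
item08,same,2-8y
item09,same,2-8y
item10,same,2-8y
item11,same,8+y
item12,same,8+y
item13,same,8+y
item14,different,0-2y
item15,different,2-8y
item16,different,2-8y
item17,different,2-8y
item18,different,2-8y
item19,different,2-8y
item20,different,8+y
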