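model,deviance,percent_explained
null,1126.6,0
environment,1048.1,13
env_human,1029.3,17
env_human_icar,798.8,56
full,541.3,100
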