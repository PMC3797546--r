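{"name":"chain-fixture","states":["S0","S1","T"],"actions":["go","stay"],"trans":[0,0,0,1,0,0,1,0,0,0,1,0,0,1,1,0,0,1],"terminal":[false,false,true],"reward_value":[0,0,1],"action_rewards":[-0.02,0.005],"start":1,"step_cap":30,"obs_map":[1,2,3],"obs_states":["S0","S1","T"]}
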