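colony,label,flightspan,deathrate,H_init,observation_days,AAOF_obs,lifespan_obs
1,Large,7.5,0.133,9000,40,18.6,22.8
2,Large,6.5,0.154,9000,40,18.4,22.3
3,Small,6.7,0.149,4500,40,23.8,26.6
4,Small,8.8,0.114,4500,40,22.2,26.4
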