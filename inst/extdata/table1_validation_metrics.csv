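metric,config,channel,direction_deg,value
avg_err_sway,off,AP,180,0.16
avg_err_sway,off,AP,225,0.19
avg_err_sway,off,ML,225,0.09
avg_err_sway,off,ML,90,0.19
avg_err_sway,1x2,AP,180,0.85
avg_err_sway,1x2,AP,225,0.27
avg_err_sway,1x2,ML,225,0.11
avg_err_sway,3x4,AP,180,0.33
avg_err_sway,3x4,AP,225,0.36
avg_err_sway,3x4,ML,225,0.10
avg_err_sway,3x4,ML,90,0.18
avg_err_sway,3x8,AP,225,0.21
avg_err_sway,3x8,ML,225,0.14
avg_err_sway,3x16,AP,225,0.30
avg_err_sway,3x16,ML,225,0.12
cc_sway,off,AP,180,0.998
cc_sway,off,AP,225,0.99
cc_sway,off,ML,225,0.97
cc_sway,off,ML,90,0.95
cc_sway,1x2,AP,180,0.94
cc_sway,1x2,AP,225,0.97
cc_sway,1x2,ML,225,0.98
cc_sway,3x4,AP,180,0.98
cc_sway,3x4,AP,225,0.95
cc_sway,3x4,ML,225,0.98
cc_sway,3x4,ML,90,0.96
cc_sway,3x8,AP,225,0.98
cc_sway,3x8,ML,225,0.95
cc_sway,3x16,AP,225,0.97
cc_sway,3x16,ML,225,0.93
avg_err_cop,off,AP,180,0.47
avg_err_cop,off,AP,225,0.21
avg_err_cop,off,ML,225,0.33
avg_err_cop,off,ML,90,0.46
avg_err_cop,1x2,AP,180,0.49
avg_err_cop,1x2,AP,225,0.26
avg_err_cop,1x2,ML,225,0.51
avg_err_cop,3x4,AP,180,0.46
avg_err_cop,3x4,AP,225,0.23
avg_err_cop,3x4,ML,225,0.51
avg_err_cop,3x4,ML,90,0.42
avg_err_cop,3x8,AP,225,0.34
avg_err_cop,3x8,ML,225,0.49
avg_err_cop,3x16,AP,225,0.27
avg_err_cop,3x16,ML,225,0.42
cc_cop,off,AP,180,0.98
cc_cop,off,AP,225,0.99
cc_cop,off,ML,225,0.98
cc_cop,off,ML,90,0.98
cc_cop,1x2,AP,180,0.97
cc_cop,1x2,AP,225,0.98
cc_cop,1x2,ML,225,0.93
cc_cop,3x4,AP,180,0.96
cc_cop,3x4,AP,225,0.99
cc_cop,3x4,ML,225,0.93
cc_cop,3x4,ML,90,0.98
cc_cop,3x8,AP,225,0.97
cc_cop,3x8,ML,225,0.92
cc_cop,3x16,AP,225,0.98
cc_cop,3x16,ML,225,0.95
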