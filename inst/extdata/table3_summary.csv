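metric,group,median,q25,q75
cmax_plasma,all,177.8,169.7,236.4
auc_plasma,all,111.3,95.7,136.5
cmax_csf,all,6.8,5.2,9.4
tmax_csf,all,1.8,1,2
auc_csf,all,26.3,16.6,43.1
t_half,all,1.7,1.5,1.9
pen_cmax_pct,all,3,2,6
pen_auc_pct,all,20,18,45
cmax_plasma,csf_sampled,177.8,169.7,236.4
auc_plasma,csf_sampled,111.3,95.7,136.5
cmax_csf,csf_sampled,7.1,3.8,9.4
tmax_csf,csf_sampled,1.2,0.9,2
auc_csf,csf_sampled,21.9,13.7,43.1
t_half,csf_sampled,1.7,1.5,1.9
pen_cmax_pct,csf_sampled,3,2,6
pen_auc_pct,csf_sampled,19,12,45
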