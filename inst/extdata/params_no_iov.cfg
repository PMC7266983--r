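variant no_iov
vmax 309.80000000000001
km 15.800000000000001
v 93.599999999999994
ka 2.3999999999999999
mtt 0.81000000000000005
nn 7.5999999999999996
emax_enz 1.2
ec50_enz 0.052999999999999999
kenz 0.0053
fmax 0.40000000000000002
ed50 17.399999999999999
f450 1
corr_vmax_km 0.59599999999999997
sigma_log 0.56899999999999995
reference_size 70
alloexp_vmax 0.75
alloexp_v 1
iiv_sd_vmax 0.55200000000000005
iiv_sd_km 0.80600000000000005
iiv_sd_v 0.085999999999999993
iiv_sd_ka 0.28699999999999998
iiv_sd_mtt 0.58799999999999997
iiv_sd_nn 0.90500000000000003
iov_sd_km 0
iov_sd_ka 0
iov_sd_mtt 0
iov_sd_f 0
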