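variant with_iov
vmax 525
km 35.299999999999997
v 87.200000000000003
ka 1.77
mtt 0.51000000000000001
nn 23.800000000000001
emax_enz 1.1599999999999999
ec50_enz 0.069900000000000004
kenz 0.0060299999999999998
fmax 0.504
ed50 67
f450 1
corr_vmax_km 0.38900000000000001
sigma_log 0.23599999999999999
reference_size 70
alloexp_vmax 0.75
alloexp_v 1
iiv_sd_vmax 0.29999999999999999
iiv_sd_km 0.35799999999999998
iiv_sd_v 0.078600000000000003
iiv_sd_ka 0.33800000000000002
iiv_sd_mtt 0.38200000000000001
iiv_sd_nn 0.77900000000000003
iov_sd_km 0.189
iov_sd_ka 0.314
iov_sd_mtt 0.56399999999999995
iov_sd_f 0.157
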