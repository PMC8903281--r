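table_id,outcome,factor_set,model,p_m,p_m_data,bf_m,bf10
pct_music,pct_correct,music_group,null,0.20,0.00,0.00,1.00
pct_music,pct_correct,music_group,music,0.20,0.89,33.23,685845
pct_music,pct_correct,music_group,music + group + music:group,0.20,0.06,0.26,46220
pct_music,pct_correct,music_group,music + group,0.20,0.05,0.20,36339
pct_music,pct_correct,music_group,group,0.20,0.00,0.00,0.12
pct_dance,pct_correct,dance_group,null,0.20,0.57,0.57,1.00
pct_dance,pct_correct,dance_group,dance,0.20,0.19,0.19,0.33
pct_dance,pct_correct,dance_group,group,0.20,0.17,0.17,0.29
pct_dance,pct_correct,dance_group,dance + group,0.20,0.06,0.06,0.10
pct_dance,pct_correct,dance_group,dance + group + dance:group,0.20,0.01,0.01,0.02
async_music,asynchrony,music_group,null,0.20,0.40,2.72,1.00
async_music,asynchrony,music_group,music,0.20,0.25,1.30,0.61
async_music,asynchrony,music_group,music + group + music:group,0.20,0.15,0.73,0.38
async_music,asynchrony,music_group,music + group,0.20,0.12,0.55,0.30
async_music,asynchrony,music_group,group,0.20,0.08,0.33,0.19
async_dance,asynchrony,dance_group,null,0.20,0.76,12.86,1.00
async_dance,asynchrony,dance_group,dance,0.20,0.13,0.59,0.17
async_dance,asynchrony,dance_group,group,0.20,0.09,0.40,0.12
async_dance,asynchrony,dance_group,dance + group,0.20,0.02,0.06,0.02
async_dance,asynchrony,dance_group,dance + group + dance:group,0.20,0.00,0.02,0.01
cdev_music,cdev,music_group,null,0.20,0.60,5.97,1.00
cdev_music,cdev,music_group,music,0.20,0.30,1.72,0.50
cdev_music,cdev,music_group,music + group + music:group,0.20,0.07,0.31,0.12
cdev_music,cdev,music_group,music + group,0.20,0.03,0.11,0.04
cdev_music,cdev,music_group,group,0.20,0.00,0.01,0.00
cdev_dance,cdev,dance_group,null,0.20,0.69,8.73,1.00
cdev_dance,cdev,dance_group,dance,0.20,0.15,0.71,0.22
cdev_dance,cdev,dance_group,group,0.20,0.12,0.56,0.18
cdev_dance,cdev,dance_group,dance + group,0.20,0.03,0.11,0.04
cdev_dance,cdev,dance_group,dance + group + dance:group,0.20,0.01,0.05,0.02
cov_music,cov,music_group,null,0.20,0.00,0.00,1.00
cov_music,cov,music_group,music + group,0.20,0.79,14.90,5.30e9
cov_music,cov,music_group,music + group + music:group,0.20,0.17,0.84,1.19e9
cov_music,cov,music_group,music,0.20,0.04,0.16,2.65e8
cov_music,cov,music_group,group,0.20,0.00,0.00,301.27
cov_dance,cov,dance_group,null,0.20,0.05,0.20,1.00
cov_dance,cov,dance_group,group,0.20,0.79,15.02,16.78
cov_dance,cov,dance_group,dance,0.20,0.12,0.56,2.62
cov_dance,cov,dance_group,dance + group,0.20,0.03,0.13,0.68
cov_dance,cov,dance_group,dance + group + dance:group,0.20,0.01,0.03,0.16
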