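{"package_version":"0.1.0","config":{"genotype_tsv":"/tmp/Rtmp3pRHzY/file46454dabab4/genotypes.tsv","phenotype_csv":"/tmp/Rtmp3pRHzY/file46454dabab4/phenotypes.csv","out_dir":"fungwas_out","min_maf":0.25,"missing_policy":"observed","sd_mode":"sample","sided":"two","n_permutations":50,"perm_seed":4,"perm_mode":"monte_carlo","thresholds":[5.6e-06,0.015],"target_expected":0.1,"ld_regions":[],"lenient":false},"n_sites_raw":504,"n_sites_tested":440,"n_strains":24,"class_split":{"low":7,"high":17},"sig_thresholds":{"target_0.1":0.000953470633104501}}
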