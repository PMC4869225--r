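account_type,retweet_impressions_rank_scale,total_impressions,amplification_multiplier
individual,76.29,67.79,96.16
organizational,11.94,15.23,0.02
media,9.34,11.15,0.01
policy,2.43,5.83,3.81
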