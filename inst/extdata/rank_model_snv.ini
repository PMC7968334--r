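# Default SNV/INDEL rank model shipped with clinwgs.
# Point values are this package's own hand-auditable defaults; the
# production laboratory weights are maintained elsewhere and are NOT
# reproduced here. Categories cover rarity, protein impact, conservation,
# inheritance support, prior clinical assertions, cohort-local observations
# and call quality. Rules are first-match in declared order.

[category.frequency]
default = 2
rule.1 = population_af missing => 4
rule.2 = population_af in [0,0.0001) => 6
rule.3 = population_af in [0.0001,0.005) => 3
rule.4 = population_af in [0.005,0.02) => 1
rule.5 = population_af in [0.02,inf) => -12

[category.consequence]
default = 0
rule.1 = consequence is stop_gained,frameshift_variant,splice_acceptor_variant,splice_donor_variant,start_lost,stop_lost => 8
rule.2 = consequence is missense_variant,inframe_deletion,inframe_insertion,protein_altering_variant => 5
rule.3 = consequence is splice_region_variant => 3
rule.4 = consequence is synonymous_variant,intron_variant,intergenic_variant => 0

[category.conservation]
default = 0
rule.1 = conservation_score in [2.5,inf) => 2
rule.2 = conservation_score in [-inf,2.5) => 0

[category.deleteriousness]
default = 0
rule.1 = deleteriousness_score in [25,inf) => 4
rule.2 = deleteriousness_score in [15,25) => 2
rule.3 = deleteriousness_score in [-inf,15) => 0

[category.inheritance]
default = 0
rule.1 = genetic_models is AD_dn,AR_hom_dn,XD_dn,XR_dn => 4
rule.2 = genetic_models is AD,AR_hom,AR_comp,AR_comp_dn,XD,XR,MT => 2

[category.clinical_significance]
default = 0
rule.1 = clinical_significance is pathogenic,likely_pathogenic => 5
rule.2 = clinical_significance is benign,likely_benign => -8

[category.local_observations]
default = 1
rule.1 = local_obs missing => 1
rule.2 = local_obs in [-inf,1) => 1
rule.3 = local_obs in [1,5) => 0
rule.4 = local_obs in [5,inf) => -6

[category.call_quality]
default = 0
rule.1 = filter_status is PASS => 1
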