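# Shared fixtures: published Weibull parameters and small builders.

pfs_osi <- weibull_params(0.033281, 0.849111)
pfs_pla <- weibull_params(0.12138, 0.96416)
os_short <- weibull_params(0.000005603, 2.931)  # 2.93-shape OS law
os_long <- weibull_params(0.0001721, 2.050)     # 2.05-shape OS law

toy_country <- function(drug = 100, bsc = 10, pall = 50, ae = 5, r = 0.03,
                        wtp = 1000, label = "toy") {
  country_inputs(label, drug, c(osimertinib = ae, placebo = 0), 1, 2, bsc,
                 pall, r, wtp,
                 c(osimertinib = 0.294, placebo = 0.781))
}

toy_utilities <- function(u_pfs = 0.791, u_pd = 0.653, with_ae = TRUE) {
  aed <- if (with_ae)
    data.frame(event = "ae", disutility = 0.05, incidence = 0.014) else NULL
  utility_inputs(u_pfs, u_pd, aed)
}
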