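# Default pipeline configuration for run_pipeline().
#
# panel: path to a panel CSV (country_id, year, disease, deaths, population,
#        asmr, one column per covariate); null = simulate a synthetic panel.
# simulate: arguments of simulation_config() (seed is mandatory).
# graph: "eac" for the built-in land-border contiguity graph, or a path to
#        an edge-list CSV (columns from, to).
# lake_edges: whether the lake-separated COD-TZA pair counts as contiguous.
# priors: overrides of default_hyperpriors(); each precision takes a
#         penalized-complexity prior with P(sigma > U) = alpha, each BYM2
#         mixing parameter a PC prior with P(rho < U) = alpha.
# inference: arguments of fit_control().

panel: null
simulate:
  seed: 1
graph: eac
lake_edges: false
vif_threshold: 5
priors: null
inference:
  n_iter: 2000
  burnin: 700
  thin: 2
  seed: 1
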