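# HCT116 colorectal carcinoma cell line: growth and radiation response
# parameters. Radiation uses the LQ arm only (alpha = alpha0 - alphaR);
# heat parameters in CEM43 units are illustrative placeholders and should
# be replaced by values fitted to heat-only clonogenic survival curves for
# quantitative heat predictions.
name: HCT116
doubling_time_h: 19.5
rate_sd_fraction: 0.05
lag_hours: 2
phase_fractions: {G1: 0.40, S: 0.35, G2: 0.20, M: 0.05}
rt: {alpha: 0.5, beta: 0.042}
ht: {alpha0: 0.1, alphaR: 0.1, beta: 0.005}
combination: {slope_a: 0.01}
dynamics: {k_delay: 0.009, p_mitoticCat: 0.2, p_senescence: 0.05}
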