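Package: ceusperf
Title: Contrast-Enhanced Ultrasound Brain Perfusion Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies regional brain perfusion from contrast-enhanced
    ultrasound (CEUS) flash-replenishment cine loops. Extracts region-of-interest
    time-intensity curves, fits the mono-exponential destruction-replenishment
    kinetic model with reliability gating, and derives microvascular flow
    velocity, transit time, and microvascular blood flow. Provides the group
    comparison scheme used in fetal hypoxia studies (Mann-Whitney U tests with
    continuity correction, Benjamini-Hochberg adjustment, day-on-circuit strata,
    central-versus-peripheral contrasts, Spearman correlations with cardiac
    output variables), the Rosenbaum crossmatch multivariate two-sample test
    with an exact minimum-weight non-bipartite matching, Doppler pulsatility
    index computation, and a synthetic-data generator emulating the cine clips
    and cohort structure of an extrauterine-support fetal lamb study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
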