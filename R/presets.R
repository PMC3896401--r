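#' Preset experiment designs
#'
#' Ready-made [sweep_spec()]s for the standard experiment grids on the
#' 75 x 200 lattice with K = 100 and 20 founding columns:
#' \describe{
#'   \item{`"fig2_boundary_speeds"`}{BLRE boundary-motion durations at r = 3,
#'     m = 0.2, p0 = 0.5. The `"methods"` variant uses durations 600, 1000,
#'     2000, 4000, 6000, 7900; the `"caption"` variant replaces 600 by 800
#'     (the source reports both lists; both are shipped). Compare against the
#'     `"pilot_expansion_time"` PhLRE reference and `"stationary_baseline"`.}
#'   \item{`"fig3_migration"`}{m in 0.01, 0.1, 0.2, 0.4 under BLRE
#'     (duration 6000), at r = 3, p0 = 0.5. The `"caption"` variant adds
#'     m = 0.001. Swap `scenario` in the base for the PhLRE counterpart.}
#'   \item{`"fig4_reproduction"`}{r in 1.1, 2, 3, 5 (caption variant:
#'     1.1, 2, 3, 4) under BLRE (duration 6000), at m = 0.2, p0 = 0.5.}
#'   \item{`"fig5_init_freq"`}{p0 in 0.01, 0.1, 0.2, 0.5 under BLRE
#'     (duration 6000), at r = 3, m = 0.2.}
#'   \item{`"stationary_baseline"`}{never-moving boundary; the 20th column is
#'     snapshotted at generation 8000 as the zero-expansion-speed reference.}
#'   \item{`"pilot_expansion_time"`}{plain PhLRE run (r = 3, m = 0.2,
#'     p0 = 0.5) whose quantity of interest is the mean expansion time.}
#' }
#'
#' @param name Preset name, see above.
#' @param variant `"methods"` or `"caption"` where the two parameter lists in
#'   the source differ; ignored otherwise.
#' @param n_replicates Replicates per combination; the desk-scale default is
#'   10 (published-style runs used 100).
#' @param base_seed,output_dir Forwarded to [sweep_spec()].
#' @return A [sweep_spec()].
#' @examples
#' preset("fig3_migration", n_replicates = 2)
#' @export
preset <- function(name = c("fig2_boundary_speeds", "fig3_migration",
                            "fig4_reproduction", "fig5_init_freq",
                            "stationary_baseline", "pilot_expansion_time"),
                   variant = c("methods", "caption"),
                   n_replicates = 10, base_seed = 1, output_dir = NULL) {
  name <- match.arg(name)
  variant <- match.arg(variant)
  blre_base <- sim_params(scenario = "BLRE", boundary_duration = 6000)
  varied <- switch(name,
    fig2_boundary_speeds = list(
      boundary_duration = if (variant == "methods")
        c(600, 1000, 2000, 4000, 6000, 7900)
      else c(800, 1000, 2000, 4000, 6000, 7900)),
    fig3_migration = list(
      m = if (variant == "methods") c(0.01, 0.1, 0.2, 0.4)
          else c(0.001, 0.01, 0.1, 0.2, 0.4)),
    fig4_reproduction = list(
      r = if (variant == "methods") c(1.1, 2, 3, 5) else c(1.1, 2, 3, 4)),
    fig5_init_freq = list(
      p0 = c(0.01, 0.1, 0.2, 0.5)),
    stationary_baseline = list(),
    pilot_expansion_time = list()
  )
  base <- switch(name,
    stationary_baseline = sim_params(scenario = "stationary",
                                     snapshot_generations = 8000),
    pilot_expansion_time = sim_params(scenario = "PhLRE"),
    blre_base
  )
  spec <- sweep_spec(base, varied, n_replicates = n_replicates,
                     base_seed = base_seed, output_dir = output_dir)
  attr(spec, "preset") <- name
  attr(spec, "variant") <- variant
  spec
}
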