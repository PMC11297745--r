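#' Full synthetic scheme-comparison experiment with default study conditions
#'
#' One-call driver for the optimized-vs-reduced measurement scheme
#' experiment: builds the rhizotron geometry and meshes, optimizes an
#' 800-configuration scheme under a 40-injection-dipole budget on a coarse
#' design mesh, derives the reduced scheme by excluding the central electrode
#' batch, creates the -25 mrad root phantom, and runs the noise-ensemble
#' comparison ([run_scheme_comparison()]).
#'
#' @param seed Master seed for the noise ensembles.
#' @param target_size,dipole_budget Scheme optimization settings.
#' @param n_noise Noise realizations per scheme.
#' @param inversion_mesh_args,design_mesh_args Lists of [build_mesh()]
#'   arguments for the inversion and design meshes.
#' @param pool_rules Candidate pool rules for [enumerate_candidates()].
#' @param batch Greedy batch size for [optimize_scheme()].
#' @return List with `comparison` (per-arm metrics and averaged fields),
#'   `scheme`, `reduced`, `phantom`, `mesh`, `design_mesh`.
#' @export
run_default_experiment <- function(seed = 1, target_size = 800,
                                   dipole_budget = 40, n_noise = 10,
                                   inversion_mesh_args = list(),
                                   design_mesh_args = list(base_h = 0.035,
                                                           refine_electrodes = FALSE),
                                   pool_rules = list(min_ab_sep = 0.2,
                                                     n_ab_dipoles = 60,
                                                     max_mn_sep = 0.15),
                                   batch = 20) {
  geom <- rhizotron_geometry()
  mesh <- do.call(build_mesh, c(list(geom), inversion_mesh_args))
  dmesh <- do.call(build_mesh, c(list(geom), design_mesh_args))
  cand <- enumerate_candidates(geom$electrodes, pool_rules)
  scheme <- optimize_scheme(dmesh, cand, target_size = target_size,
                            dipole_budget = dipole_budget, batch = batch)
  reduced <- exclude_electrodes(scheme, geom$central_batch)
  phantom <- make_phantom(phantom_spec(), mesh)
  comparison <- run_scheme_comparison(mesh, phantom, scheme, reduced,
                                      n_noise = n_noise, seed = seed)
  list(comparison = comparison, scheme = scheme, reduced = reduced,
       phantom = phantom, mesh = mesh, design_mesh = dmesh, geometry = geom)
}
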