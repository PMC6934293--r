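# Shared fixtures: the bare-platinum coil constants, brute-force oracles,
# and a lazily built (then cached) reduced deployment pipeline shared by
# the protocol and acceptance tests.

axium <- list(D1 = 0.0381, D2 = 0.2921, Ew = 230, Gw = 82)

# brute-force gliding-box lacunarity: enumerate every box position
brute_lacunarity <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  if (r > nr || r > nc) return(NA_real_)
  masses <- c()
  for (i in 1:(nr - r + 1))
    for (j in 1:(nc - r + 1))
      masses <- c(masses, sum(img[i:(i + r - 1), j:(j + r - 1)]))
  mu <- mean(masses)
  if (mu == 0) return(1)
  (mean(masses^2) - mu^2) / mu^2 + 1
}

# cache for the expensive reduced-scale deployment pipeline
.pipeline_env <- new.env(parent = emptyenv())

reduced_case <- function() {
  if (is.null(.pipeline_env$case))
    .pipeline_env$case <- make_synthetic_aneurysm(5, 3, vessel_length = 25,
                                                  mesh_n = 36)
  .pipeline_env$case
}

# packaging -> advancement -> deployment of the reduced 5 mm x 20 mm coil
reduced_pipeline <- function() {
  if (!is.null(.pipeline_env$pipe)) return(.pipeline_env$pipe)
  spec <- coil_spec(D3 = 5, l = 20)
  case <- reduced_case()
  pre <- make_preshape(spec, h = 0.5)
  props <- coil_beam_properties(spec$D1, spec$D2, spec$l)
  cath <- build_catheter(case$centerline, spec$D2, spec$l, tip_inset = 1)
  model <- build_beam_model(position_preshape(pre, cath, 0), props)
  cfg <- solver_config()
  packaged <- package_coil(model, cath, cfg)
  advanced <- advance_coil(model, packaged, cath, cfg)
  deployed <- deploy_coil(model, advanced, cath, case, cfg)
  .pipeline_env$pipe <- list(spec = spec, case = case, props = props,
                             cath = cath, model = model, cfg = cfg,
                             packaged = packaged, advanced = advanced,
                             deployed = deployed)
  .pipeline_env$pipe
}

# straight- and curved-catheter advancement energies (shared fixture)
advancement_energies <- function() {
  if (!is.null(.pipeline_env$adv)) return(.pipeline_env$adv)
  spec <- coil_spec(D3 = 5, l = 20)
  pre <- make_preshape(spec, h = 0.5)
  props <- coil_beam_properties(spec$D1, spec$D2, spec$l)
  one <- function(pts) {
    cath <- build_catheter(centerline(pts), spec$D2, spec$l)
    m <- build_beam_model(position_preshape(pre, cath, 0), props)
    cfg <- solver_config()
    st <- package_coil(m, cath, cfg)
    st2 <- advance_coil(m, st, cath, cfg)
    c(packaged = attr(st, "packaged_energy"),
      advanced = st2$energy[["strain"]])
  }
  straight <- one(cbind(seq(-25, 0, length.out = 60), 0, 0))
  ang <- seq(-2.5, 0, length.out = 60)
  curved <- one(cbind(10 * sin(ang), 0, -10 * (1 - cos(ang))))
  .pipeline_env$adv <- list(straight = straight, curved = curved)
  .pipeline_env$adv
}

mdist_segments <- function(pts, path) {
  coildeploy:::cpp_min_dist_to_segments(
    pts, path[-nrow(path), , drop = FALSE], path[-1, , drop = FALSE])
}
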