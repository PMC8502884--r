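# Shared expensive fixtures, built once per test session.  The reference
# phantom run reproduces the package's default study conditions (40^3 grid of
# 2.5 mm voxels, two-shell 4+30+60 protocol, snr 30, fixed seeds); the graded
# run lowers the free-water level in one half of the edema block so that both
# trackers traverse part of it and the DN / N-only contrast is populated.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

phantom_run <- function(key, spec, count = 3000L, seed = 42L) {
  memo(key, function() {
    gt <- build_phantom(spec)
    scheme <- make_protocol(seed = seed)
    dwi <- simulate_dwi(gt, scheme, snr = spec$snr, rng_seed = seed + 1L)
    tf <- fit_dti(dwi, scheme, mask = gt$analysis)
    nf <- fit_noddi(dwi, scheme, gt$analysis, init_mu = tf$e1$data)
    rois <- roi_set(include = unname(gt$include), exclude = unname(gt$exclude))
    guard <- nf$fitted & !is.na(nf$vf_iso$data) & nf$vf_iso$data < 0.95
    valid <- image_grid(array(as.numeric(guard), dim = dim(guard)),
                        affine = gt$affine)
    rule_fa <- stop_rule(tf$fa, "floor", 0.20)
    rule_odi <- stop_rule(nf$odi, "ceiling", 0.45)
    tr_dti <- track(tf$e1, rule_fa, gt$include$inferior, target_count = count,
                    rng_seed = seed + 2L, rois = rois)
    tr_noddi <- track(nf$mu, rule_odi, gt$include$inferior,
                      target_count = count, rng_seed = seed + 3L,
                      rois = rois, valid_mask = valid)
    list(gt = gt, scheme = scheme, dwi = dwi, tf = tf, nf = nf,
         rois = rois, valid = valid, tr_dti = tr_dti, tr_noddi = tr_noddi)
  })
}

default_run <- function() {
  phantom_run("default", phantom_spec(), count = 3000L, seed = 42L)
}

graded_run <- function() {
  phantom_run("graded", phantom_spec(edema_mild_viso = 0.6), count = 500L,
              seed = 42L)
}
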