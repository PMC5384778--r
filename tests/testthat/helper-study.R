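# Shared phantom registration study used by the comparative acceptance
# checks (CC ordering across methods, thigh-error comparison, denoising
# effect). Computed once per test run and cached.

.study_cache <- new.env(parent = emptyenv())

phantom_study <- function(seeds = 1:10, size = 48, spacing = 3) {
  key <- paste0("s", paste(seeds, collapse = "_"), "_", size)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  rows <- lapply(seeds, function(seed) {
    ph <- rtfuse::make_phantom(seed = seed, size = size, spacing = spacing,
                               global = "affine", local_amplitude = 4,
                               roi_amplitude = 12, n_impulses = 120)
    tgt <- rtfuse::median_denoise(ph$target)
    src <- rtfuse::median_denoise(ph$source)

    aff <- rtfuse::register_linear(tgt, src, "affine",
                                   rtfuse::reg_config(max_iter = 15))
    ffd <- rtfuse::register_ffd(tgt, src,
             rtfuse::reg_config(max_iter = 8, init_transform = aff$transform))
    mp <- rtfuse::register_multiphase(tgt, src, ph$roi,
            ph$landmarks_target, ph$landmarks_source,
            rtfuse::reg_config(control_spacing0 = 40, pyramid_levels = 3,
                               init_transform = aff$transform),
            rtfuse::reg_config(max_iter = 8))

    # no-denoise pipeline on the raw noisy pair
    aff0 <- rtfuse::register_linear(ph$target, ph$source, "affine",
                                    rtfuse::reg_config(max_iter = 15))
    ffd0 <- rtfuse::register_ffd(ph$target, ph$source,
              rtfuse::reg_config(max_iter = 8, init_transform = aff0$transform))

    ft <- rtfuse::transform_to_field(ph$truth_transform, tgt)
    pts <- rtfuse:::grid_world_points(tgt)
    thigh <- array(rtfuse:::roi_contains(ph$roi, pts), dim(tgt$voxels)) &
      (ph$labels_target$voxels %in% c(4, 5))
    thigh_err <- function(fit) {
      e <- rtfuse::transform_to_field(fit$transform, tgt) - ft
      mean(sqrt(apply(e^2, 1:3, sum))[thigh])
    }
    data.frame(
      seed = seed,
      cc_none = rtfuse::pearson_cc(tgt, src),
      cc_affine = rtfuse::pearson_cc(tgt, rtfuse::warp_image(src, aff$transform, tgt)),
      cc_ffd = rtfuse::pearson_cc(tgt, rtfuse::warp_image(src, ffd$transform, tgt)),
      cc_multiphase = rtfuse::pearson_cc(tgt, rtfuse::warp_image(src, mp$transform, tgt)),
      cc_ffd_nodenoise = rtfuse::pearson_cc(ph$target,
        rtfuse::warp_image(ph$source, ffd0$transform, ph$target)),
      thigh_ffd = thigh_err(ffd),
      thigh_multiphase = thigh_err(mp),
      nmi_init_ffd = ffd$initial_metric,
      nmi_final_ffd = ffd$final_metric)
  })
  out <- do.call(rbind, rows)
  .study_cache[[key]] <- out
  out
}
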