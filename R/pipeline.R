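#' Configuration of the end-to-end trans-SV workflow
#'
#' Bundles everything [run_pipeline()] needs to go from a source-region Hi-C
#' matrix to cross-breakpoint neoloop candidates: fit the source region,
#' bridge classes to the target region through tracks, assemble the hybrid
#' (possibly circular) locus, predict its contact map, and call candidates.
#' Every stochastic stage receives a seed derived deterministically from the
#' master seed and the stage name.
#'
#' @param source_matrix `contact_matrix` (or path to one) of the SV-free
#'   source region.
#' @param source_region,target_region lists `list(chrom =, start =)` locating
#'   the fitted and the unfitted region (0-based bp).
#' @param source_tracks,target_tracks named lists of [binned_track()]s
#'   (raw tracks are binarized with the top-quartile rule).
#' @param segments hybrid segment table for [assemble_hybrid()]; a `source`
#'   column marks each segment `"fit"` (binding from the source fit) or
#'   `"transfer"` (binding from the transferred profile).
#' @param prismr a [prismr_config()].
#' @param decay a [decay_params()].
#' @param topology assembly topology, `"circular"` for ecDNA-like SVs.
#' @param buffer_bp inert buffer closing a circular assembly.
#' @param transfer_threshold couple-inclusion threshold (default 0.2).
#' @param z_threshold candidate-calling z cut.
#' @param seed master seed.
#' @param out_dir artifact directory (`NULL`: nothing written).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(source_matrix, source_region, target_region,
                            source_tracks, target_tracks, segments,
                            prismr, decay = decay_params(),
                            topology = "circular", buffer_bp = 80000,
                            transfer_threshold = 0.2, z_threshold = 2,
                            seed = 1L, out_dir = NULL) {
  structure(
    list(source_matrix = source_matrix, source_region = source_region,
         target_region = target_region, source_tracks = source_tracks,
         target_tracks = target_tracks, segments = segments,
         prismr = prismr, decay = decay, topology = topology,
         buffer_bp = buffer_bp, transfer_threshold = transfer_threshold,
         z_threshold = z_threshold, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage_seed <- function(master, stage) {
  # deterministic per-stage seed below 2^31
  (master * 1000003L + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the trans-SV prediction workflow end to end
#'
#' fit -> transfer -> assemble -> predict -> call candidates -> report.
#' The source region is fitted with [sa_fit()]; the inferred classes are
#' correlated with the source tracks ([build_transfer_model()]) and bridged
#' to the target region ([transfer_classes()]); the hybrid locus is assembled
#' ([assemble_hybrid()]) with per-bin binding taken from the fit (as 0/1
#' class indicators) or the transferred probabilities per segment; the
#' contact map is predicted under the assembly topology
#' ([predict_neo_contacts()]) and candidate neoloops called
#' ([call_candidate_neoloops()]). When `out_dir` is set, all artifacts plus a
#' machine-readable manifest (config hash, seeds, versions) are written.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `fit`, `transfer_model`, `profile`, `assembly`,
#'   `predicted`, `candidates`, `report` (one-row tibble), `manifest`.
#' @export
run_pipeline <- function(cfg) {
  source_matrix <- with_stage("read", {
    if (is.character(cfg$source_matrix)) read_contact_matrix(cfg$source_matrix)
    else cfg$source_matrix
  })

  binarize_all <- function(tracks) {
    lapply(tracks, function(t) {
      if (track_kind(t) == "indicator") t else binarize_track(t, "quantile")
    })
  }
  src_tracks <- with_stage("tracks", binarize_all(cfg$source_tracks))
  if (length(cfg$target_tracks) == 0) {
    abort("pipeline stage 'transfer' failed: no target tracks supplied.")
  }
  tgt_tracks <- with_stage("tracks", binarize_all(cfg$target_tracks))

  fit <- with_stage("fit", {
    pc <- cfg$prismr
    pc$seed <- stage_seed(cfg$seed, "fit")
    sa_fit(source_matrix, pc)
  })

  model <- with_stage("transfer", build_transfer_model(
    fit$polymer, src_tracks, threshold = cfg$transfer_threshold
  ))
  profile <- with_stage("transfer", transfer_classes(model, tgt_tracks))

  assembly <- with_stage("assemble", assemble_hybrid(
    cfg$segments, buffer_bp = cfg$buffer_bp, topology = cfg$topology,
    bin_size = attr(source_matrix, "bin_size")
  ))

  binding <- with_stage("assemble", hybrid_binding(
    assembly, cfg, fit, profile, attr(source_matrix, "bin_size")
  ))

  predicted <- with_stage("predict", predict_neo_contacts(assembly, binding, cfg$decay))
  candidates <- with_stage("call", call_candidate_neoloops(
    predicted, assembly, z_threshold = cfg$z_threshold
  ))

  report <- tibble(
    fit_correlation = fit$correlation,
    fit_cost = fit$cost,
    n_included_couples = sum(model$included),
    n_candidates = nrow(candidates),
    n_cross_breakpoint = sum(candidates$crosses_breakpoint),
    top_crosses_breakpoint = if (nrow(candidates)) candidates$crosses_breakpoint[1] else NA
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("neofold")),
    r_version = R.version.string,
    master_seed = cfg$seed,
    stage_seeds = list(fit = stage_seed(cfg$seed, "fit")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  )

  if (!is.null(cfg$out_dir)) {
    with_stage("write", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      prov <- list(seed = cfg$seed, config_hash = manifest$config_hash)
      write_binding_profile(fit$polymer, file.path(cfg$out_dir, "fit_binding.tsv"))
      readr::write_tsv(model, file.path(cfg$out_dir, "transfer_model.tsv"))
      readr::write_tsv(profile, file.path(cfg$out_dir, "class_profile.tsv"))
      write_contact_matrix(predicted, file.path(cfg$out_dir, "predicted_matrix.tsv"),
                           provenance = prov)
      readr::write_tsv(candidates, file.path(cfg$out_dir, "neoloop_candidates.tsv"))
      readr::write_tsv(report, file.path(cfg$out_dir, "report.tsv"))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE)
    })
  }

  list(fit = fit, transfer_model = model, profile = profile,
       assembly = assembly, predicted = predicted, candidates = candidates,
       report = report, manifest = manifest)
}

# Per-hybrid-bin binding rows: "fit" segments use the source fit's class
# indicators at the matching reference bins, "transfer" segments the
# transferred probabilities at the target's bins; buffers zero.
hybrid_binding <- function(assembly, cfg, fit, profile, bin_size) {
  M <- fit$polymer$n_classes
  P_fit <- (fit$polymer$binding > 0) * 1
  P_tr <- profile_matrix(profile)
  if (ncol(P_tr) != M) abort("transferred profile class count mismatch.")
  src <- cfg$segments$source %||% rep("fit", nrow(cfg$segments))
  B <- matrix(0, assembly$n_bins, M)
  bm <- assembly$bin_map
  for (k in seq_len(assembly$n_bins)) {
    if (bm$is_buffer[k]) next
    seg <- bm$segment[k]
    region <- if (src[seg] == "fit") cfg$source_region else cfg$target_region
    tab <- if (src[seg] == "fit") P_fit else P_tr
    bin <- (bm$ref_start[k] - region$start) / bin_size + 1
    if (bin < 1 || bin > nrow(tab) || bm$chrom[k] != region$chrom) {
      abort(sprintf("hybrid bin %d (%s:%s) falls outside its source region.",
                    k, bm$chrom[k], format(bm$ref_start[k], scientific = FALSE)))
    }
    B[k, ] <- tab[bin, ]
  }
  B
}
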