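#' Study configuration
#'
#' Bundles a species/modality preset, channel roles, segmentation
#' parameters and the subject-to-file map for [run_pipeline()]. Presets fix
#' the pairing distance to the convention for the material: 1 um for human
#' confocal and human array tomography, 0.5 um for mouse.
#'
#' @param files tibble with columns `group, subject, path` (one stack per
#'   row; a subject may have several stacks which are averaged).
#' @param preset `"mouse"`, `"human_confocal"` or `"human_at"`.
#' @param channels length-2 named character vector, `c(pre = ..., post =
#'   ...)`, naming the stack channels to use.
#' @param seg named list of [seg_params()] per channel role (`pre`,
#'   `post`); a single `seg_params` is used for both.
#' @param roi_size_um neuropil ROI size, um.
#' @param max_dist_um override of the preset pairing distance.
#' @param seed integer seed recorded in the run log.
#' @return A `study_config` list.
#' @export
study_config <- function(files,
                         preset = c("mouse", "human_confocal", "human_at"),
                         channels = c(pre = "pre", post = "post"),
                         seg = seg_params(),
                         roi_size_um = 10,
                         max_dist_um = NULL,
                         seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(is.data.frame(files),
            all(c("group", "subject", "path") %in% names(files)))
  if (inherits(seg, "seg_params")) seg <- list(pre = seg, post = seg)
  dist <- max_dist_um %||%
    switch(preset, mouse = 0.5, human_confocal = 1.0, human_at = 1.0)
  structure(list(files = as_tibble(files), preset = preset,
                 channels = channels, seg = seg,
                 roi_size_um = roi_size_um, max_dist_um = dist,
                 seed = seed),
            class = "study_config")
}

#' Read a study config from YAML
#'
#' Expects top-level keys `preset`, `channels` (`pre`, `post`), optional
#' `roi_size_um`, `max_dist_um`, `seed`, and `files`: a list of
#' `{group, subject, path}` entries.
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  files <- purrr::map_dfr(x$files, as_tibble)
  study_config(files,
               preset = x$preset %||% "mouse",
               channels = c(pre = x$channels$pre %||% "pre",
                            post = x$channels$post %||% "post"),
               roi_size_um = x$roi_size_um %||% 10,
               max_dist_um = x$max_dist_um,
               seed = x$seed %||% 1L)
}

#' Run the full synapse-density pipeline over a study
#'
#' For every stack file: read, segment the pre and post channels, apply the
#' consecutive-section persistence filter, pair puncta by center distance
#' (preset-dependent radius), tile the field into neuropil ROIs and compute
#' densities. Stack-level values are then averaged per subject (a subject's
#' stacks are its technical replicates), the aggregation convention for
#' per-animal reporting. Outputs are deterministic for a fixed config:
#' rerunning gives identical tables, and input file order does not matter.
#'
#' @param cfg a [study_config()]; every referenced file must exist (the
#'   first missing path aborts the run by name).
#' @return A `synq_pipeline_result`: list with `per_stack` and
#'   `per_subject` tibbles, the `config`, and `log` (package version +
#'   config echo).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  missing <- cfg$files$path[!file.exists(cfg$files$path)]
  if (length(missing) > 0) {
    abort(sprintf("input file not found: %s", missing[1]))
  }
  files <- dplyr::arrange(cfg$files, .data$group, .data$subject, .data$path)
  per_stack <- purrr::map_dfr(seq_len(nrow(files)), function(i) {
    row <- files[i, ]
    res <- tryCatch(
      analyze_stack_file(row$path, cfg),
      error = function(e) {
        abort(sprintf("stage failed for '%s': %s", row$path,
                      conditionMessage(e)))
      })
    dplyr::bind_cols(row, res)
  })
  per_subject <- per_stack |>
    dplyr::group_by(.data$group, .data$subject) |>
    dplyr::summarise(n_stacks = dplyr::n(),
                     dplyr::across(dplyr::where(is.numeric) &
                                     !dplyr::any_of("n_stacks"), mean),
                     .groups = "drop")
  structure(list(
    per_stack = per_stack,
    per_subject = per_subject,
    config = cfg,
    log = list(package_version = as.character(utils::packageVersion("synaptiq")),
               seed = cfg$seed, preset = cfg$preset,
               max_dist_um = cfg$max_dist_um,
               roi_size_um = cfg$roi_size_um,
               n_files = nrow(files))),
    class = "synq_pipeline_result")
}

analyze_stack_file <- function(path, cfg) {
  stack <- read_stack(path)
  d <- dim(stack)
  px <- attr(stack, "pixel_size_um")
  sp <- attr(stack, "spacing_um")
  pre <- extract_objects(stack, cfg$channels[["pre"]], cfg$seg$pre) |>
    persistence_filter()
  post <- extract_objects(stack, cfg$channels[["post"]], cfg$seg$post) |>
    persistence_filter()
  pairing <- pair_puncta(pre, post, cfg$max_dist_um)
  grid <- make_neuropil_rois(c(d[1] * px, d[2] * px), depth_um = d[3] * sp,
                             roi_size_um = cfg$roi_size_um)
  dens <- compute_densities(pairing,
                            setNames(list(pre, post),
                                     c(cfg$channels[["pre"]],
                                       cfg$channels[["post"]])),
                            grid)
  dens$summary
}

#' @export
print.synq_pipeline_result <- function(x, ...) {
  cat(sprintf("<synq_pipeline_result> %d stacks, %d subjects (%s preset, pairing %g um)\n",
              nrow(x$per_stack), nrow(x$per_subject), x$config$preset,
              x$config$max_dist_um))
  print(x$per_subject)
  invisible(x)
}

#' @export
tidy.synq_pipeline_result <- function(x, ...) x$per_subject

#' Percent change of a value relative to a reference
#'
#' `(reference - value) / reference * 100`: positive numbers are
#' reductions. The complementary convention, percent of reference
#' (`value / reference * 100`), is reported alongside by [group_stats()]
#' because published summaries use both.
#'
#' @param reference reference (control) value.
#' @param value comparison value.
#' @return Percent change.
#' @export
percent_change <- function(reference, value) {
  (reference - value) / reference * 100
}
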