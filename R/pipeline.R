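# End-to-end pipeline orchestration and bit-stable text file I/O.

#' Pipeline configuration
#'
#' Assembles the fully resolved configuration of a pipeline run; every
#' artifact directory records this object (plus the seed) as JSON.
#'
#' @param sg_symbol Space-group symbol.
#' @param cell A `unit_cell`.
#' @param d_min High-resolution limit (Angstrom).
#' @param n_sites Number of anomalous sites in the simulated truth.
#' @param f_double_prime Site f'' in electrons.
#' @param protein_scale RMS protein structure amplitude (electrons).
#' @param n_images,mean_obs,scale_sigma,p_min,noise_gain,cell_jitter
#'   Simulator block (see [simulate_images()]).
#' @param distance_schedule Data frame run/true_mm/assumed_mm.
#' @param n_iter,z_max,scale_form Merge block.
#' @param cc_min Image-selection threshold.
#' @param n_shells Metrics block.
#' @param min_count,tol Consensus block.
#' @param map_dims Grid for Patterson/difference-Fourier maps.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `sfx_config`.
#' @export
pipeline_config <- function(sg_symbol = "P41212",
                            cell = tetragonal_cell(58.6, 151.3),
                            d_min = 3.5, n_sites = 17,
                            f_double_prime = 0.7, protein_scale = 650,
                            n_images = 400, mean_obs = 60,
                            scale_sigma = 0.3, p_min = 0.3,
                            noise_gain = 1, cell_jitter = 5e-4,
                            distance_schedule = NULL,
                            n_iter = 1, z_max = 4, scale_form = "sum_ratio",
                            cc_min = 0, n_shells = 5,
                            min_count = 3, tol = 1.5,
                            map_dims = c(16, 16, 40), seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sfx_config"
  cfg
}

#' Run the full pipeline
#'
#' simulate -> refine geometry -> scale/merge -> reject outliers ->
#' metrics -> select images -> anomalous maps -> consensus, writing every
#' stage's artifact into `outdir` as plain text (JSON-lines observations,
#' CSV tables, HKLF4 merged data, map dumps, .res site lists) plus a run
#' log with per-stage counts.  Deterministic for a given seed.  With
#' `f_double_prime = 0` the consensus stage is skipped with a warning.
#'
#' @param config An `sfx_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the principal in-memory results and
#'   `log` (per-stage counts).
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  jsonlite::write_json(config[setdiff(names(config), "cell")],
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  sg <- expand_ops(config$sg_symbol)
  gt <- build_ground_truth(config$cell, sg, n_sites = config$n_sites,
                           f_double_prime = config$f_double_prime,
                           protein_scale = config$protein_scale,
                           d_min = config$d_min, seed = config$seed)
  write_res_sites(gt$sites, file.path(outdir, "truth_sites.res"))
  still <- simulate_images(gt, n_images = config$n_images,
                           mean_obs = config$mean_obs,
                           scale_sigma = config$scale_sigma,
                           p_min = config$p_min,
                           noise_gain = config$noise_gain,
                           distance_schedule = config$distance_schedule,
                           cell_jitter = config$cell_jitter,
                           seed = config$seed + 1)
  write_observations(still, file.path(outdir, "observations.jsonl"))
  log$images_simulated <- nrow(still$images)
  log$observations <- nrow(still$obs)

  dist_ref <- refine_run_distances(still, reference_cell = config$cell)
  utils::write.csv(dist_ref$table, file.path(outdir, "distances.csv"),
                   row.names = FALSE)
  still <- dist_ref$images

  sm <- two_pass_merge(still, n_iter = config$n_iter,
                       form = config$scale_form, anomalous = TRUE)
  log$images_usable <- sum(sm$scales$usable)
  log$images_unusable <- sum(!sm$scales$usable)
  rej <- reject_outliers(sm$obs_scaled, sm$merged, z_max = config$z_max)
  log$observations_rejected <- rej$n_rejected
  merged <- merge_unscaled(rej$obs, still$cell, still$sg, anomalous = TRUE)
  write_hklf4(merged, file.path(outdir, "merged.hkl"))
  utils::write.csv(as.data.frame(merged), file.path(outdir, "merged.csv"),
                   row.names = FALSE, na = "")

  shells <- shell_stats(merged, n_shells = config$n_shells)
  write_shell_csv(shells, file.path(outdir, "shells.csv"))

  sel <- select_images(sm$scales, config$cc_min)
  writeLines(as.character(sel), file.path(outdir, "selected_images.txt"))
  log$images_selected <- length(sel)
  log$selection_rate_pct <- percent_rate(length(sel), nrow(still$images))

  an <- anomalous_stats(merged)
  log$r_ano <- an$r_ano; log$cc_ano <- an$cc_ano
  deltas <- bijvoet_deltas(merged, phases = gt$refl)
  pat <- patterson_map(deltas, dims = config$map_dims)
  write_map_text(pat, file.path(outdir, "patterson.txt"))
  dfo <- difference_fourier(deltas, dims = config$map_dims)
  write_map_text(dfo, file.path(outdir, "difference_fourier.txt"))
  utils::write.csv(map_peaks(dfo, min_height = 3),
                   file.path(outdir, "fourier_peaks.csv"),
                   row.names = FALSE)
  log$s_ano_truth_sites <- s_ano(dfo, gt$sites)

  consensus <- NULL
  if (config$f_double_prime > 0 && config$n_sites > 0) {
    sols <- simulate_substructure_solutions(gt$sites, sg, still$cell,
                                            seed = config$seed + 2)
    consensus <- consensus_filter(sols, sg, still$cell,
                                  min_count = config$min_count,
                                  tol = config$tol)
    if (!is.null(consensus$sites))
      write_res_sites(consensus$sites,
                      file.path(outdir, "consensus_sites.res"))
    log$consensus_sites <- if (is.null(consensus$sites)) 0L
    else nrow(consensus$sites)
  } else {
    warning("no anomalous signal configured; consensus stage skipped")
  }
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(gt = gt, still = still, scaled = sm, merged = merged,
                 shells = shells, selected = sel, deltas = deltas,
                 patterson = pat, fourier = dfo, consensus = consensus,
                 log = log))
}

#' Percentage rate from counts
#'
#' Rounds `100 * n / total` to one decimal, the convention used for
#' hit-rate / indexing-rate bookkeeping in run logs.
#'
#' @param n,total Counts.
#' @return Percentage rounded to one decimal.
#' @export
percent_rate <- function(n, total) round(100 * n / total, 1)

# --- SHELX HKLF4 fixed-width text ------------------------------------------

#' Write reflections as SHELX HKLF4 fixed-width text
#'
#' Format 3I4,2F8.2 (h k l I sigma) with a 0 0 0 terminator line.  When
#' intensities exceed the field width all I/sigma are rescaled by a
#' common factor to fit, as SHELX conventions allow.
#'
#' @param merged An `sfx_merged` or data frame with h, k, l, I, sigma.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_hklf4 <- function(merged, path) {
  x <- as.data.frame(merged)
  I <- x$I; s <- x$sigma
  mx <- max(abs(c(I, s)), 1)
  fac <- if (mx > 9999.99) 9999.99 / mx else 1
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", x$h, x$k, x$l, I * fac, s * fac)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0, 0, 0, 0, 0)), path)
  invisible(path)
}

#' Parse SHELX HKLF4 fixed-width text
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return Data frame h, k, l, I, sigma; parsing stops at the 0 0 0
#'   terminator.  Malformed lines raise an error naming the line number.
#' @export
parse_hklf4 <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- matrix(NA_real_, length(lines), 5)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (nchar(ln) < 28)
      stop(sprintf("malformed HKLF4 line %d: expected 3I4,2F8.2", i))
    v <- suppressWarnings(as.numeric(c(
      substr(ln, 1, 4), substr(ln, 5, 8), substr(ln, 9, 12),
      substr(ln, 13, 20), substr(ln, 21, 28))))
    if (any(is.na(v)))
      stop(sprintf("malformed HKLF4 line %d: expected 3I4,2F8.2", i))
    if (all(v[1:3] == 0)) break
    out[i, ] <- v
  }
  out <- out[!is.na(out[, 1]), , drop = FALSE]
  data.frame(h = as.integer(out[, 1]), k = as.integer(out[, 2]),
             l = as.integer(out[, 3]), I = out[, 4], sigma = out[, 5])
}

# --- JSON-lines observation format -----------------------------------------

#' Write/read per-image observations as JSON lines
#'
#' One image per line:
#' `{"image_id":..,"run_id":..,"distance_mm":..,"cell":[a,b,c,al,be,ga],`
#' `"obs":[[h,k,l,I,sigma],...]}` - simple, streamable and diffable.
#'
#' @param still An `sfx_still_set`.
#' @param path Output file.
#' @return `write_observations`: the path, invisibly.
#'   `read_observations`: an `sfx_still_set` (without truth columns; cell
#'   and space group must be supplied to re-attach them).
#' @export
write_observations <- function(still, path) {
  con <- file(path, "w"); on.exit(close(con))
  im <- still$images
  obs_by <- split(still$obs[, c("h", "k", "l", "I", "sigma")],
                  still$obs$image_id)
  for (i in seq_len(nrow(im))) {
    o <- obs_by[[as.character(im$image_id[i])]]
    rec <- list(image_id = im$image_id[i], run_id = im$run[i],
                distance_mm = im$assumed_mm[i],
                cell = c(im$a[i], im$b[i], im$c[i], 90, 90, 90),
                obs = unname(as.matrix(o)))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_observations
#' @param cell,sg Crystal form to attach on read.
#' @export
read_observations <- function(path, cell = NULL, sg = NULL) {
  lines <- readLines(path)
  ims <- NULL; obs <- NULL
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln)
    ims <- rbind(ims, data.frame(image_id = rec$image_id,
                                 run = rec$run_id,
                                 a = rec$cell[1], b = rec$cell[2],
                                 c = rec$cell[3],
                                 assumed_mm = rec$distance_mm))
    m <- rec$obs
    obs <- rbind(obs, data.frame(image_id = rec$image_id, h = m[, 1],
                                 k = m[, 2], l = m[, 3], I = m[, 4],
                                 sigma = m[, 5]))
  }
  structure(list(images = ims, obs = obs, cell = cell, sg = sg),
            class = "sfx_still_set")
}
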