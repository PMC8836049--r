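# ---- the central analysis object ----------------------------------------------

#' Full early-unfolding analysis of a trajectory
#'
#' Runs the package's analysis stages over one trajectory and collects the
#' results in a single object: backbone RMSD and per-residue RMSF,
#' essential-dynamics PCA with projections on the top modes, native contact
#' fraction Q for the whole protein, each domain and each region, the
#' ensemble contact map, the secondary-structure matrix with ordered
#' beta-loss events, aromatic-pair persistence with cluster-formation
#' detection, and (when two domains are named) closure/twist motion
#' fractions.
#'
#' @param traj an `mdu_trajectory`.
#' @param regions an `mdu_regions` map (default: the built-in HGDC map).
#' @param stride frame sampling stride for contact/SS/aromatic stages.
#' @param cutoff residue contact cutoff in Angstrom (default 6.5).
#' @param min_separation minimum contact sequence separation (default 1).
#' @param band aromatic interaction band in Angstrom (default 4.5..7.0).
#' @param ss_threshold,ss_persistence,ss_window event-detection parameters,
#'   see [detect_unfolding_events()].
#' @param fixed_domain,moving_domain optional region names for the
#'   interdomain motion stage (e.g. "C_td", "N_td").
#' @param include_his treat histidine as aromatic (default FALSE).
#' @return An object of class `unfolding_analysis`; see the print and
#'   summary methods.
#' @export
unfolding_analysis <- function(traj, regions = default_regions(), stride = 1L,
                               cutoff = 6.5, min_separation = 1L,
                               band = AROMATIC_BAND, ss_threshold = 50,
                               ss_persistence = 5L, ss_window = 5L,
                               fixed_domain = NULL, moving_domain = NULL,
                               include_his = FALSE) {
  stopifnot(inherits(traj, "mdu_trajectory"))
  topo <- traj$topology
  multi <- n_frames(traj) >= 2L

  res <- list(call = match.call(),
              params = list(stride = stride, cutoff = cutoff,
                            min_separation = min_separation, band = band,
                            ss_threshold = ss_threshold,
                            ss_persistence = ss_persistence,
                            ss_window = ss_window),
              regions = regions, times = traj$times,
              n_res = n_residues(topo))

  res$rmsd <- rmsd_series(traj)
  if (multi) {
    res$rmsf <- rmsf_per_residue(traj)
    res$pca <- pca_essential(traj)
    res$projections <- project_frames(traj, res$pca,
                                      k = min(2L, length(res$pca$values)))
  }

  res$q_whole <- contact_fraction_series(traj, stride, cutoff = cutoff,
                                         min_separation = min_separation)
  res$q_regions <- list()
  for (r in regions$name) {
    qs <- tryCatch(contact_fraction_series(traj, stride, region = r,
                                           regions = regions, cutoff = cutoff,
                                           min_separation = min_separation),
                   error = function(e) NULL)
    if (!is.null(qs)) res$q_regions[[r]] <- qs
  }
  res$contact_map <- ensemble_contact_map(traj, stride, cutoff, min_separation)

  res$ss <- ss_timeseries(traj, stride)
  res$events <- detect_unfolding_events(res$ss, regions, ss_threshold,
                                        ss_persistence, ss_window)

  aro <- aromatic_residues(topo, include_his)
  if (nrow(aro) >= 2) {
    prs <- utils::combn(aro$resno, 2)
    res$aromatic_persistence <- data.frame(
      res_a = prs[1, ], res_b = prs[2, ],
      persistence_pct = vapply(seq_len(ncol(prs)), function(k)
        persistence_percentage(traj, prs[1, k], prs[2, k], stride, band),
        numeric(1)))
    res$reference_clusters <- detect_aromatic_clusters(topo, traj$coords[[1]],
                                                       band = band,
                                                       include_his = include_his)
    res$cluster_events <- cluster_formation_events(traj, stride = stride,
                                                   band = band,
                                                   include_his = include_his)
  }

  if (!is.null(fixed_domain) && !is.null(moving_domain) && multi) {
    res$motion <- suppressWarnings(
      motion_fraction(traj, fixed_domain, moving_domain, regions, stride))
  }
  class(res) <- "unfolding_analysis"
  res
}

#' @export
print.unfolding_analysis <- function(x, ...) {
  cat("Early-unfolding trajectory analysis\n")
  cat(sprintf("  %d residues, %d frames (%.4g..%.4g ns)\n", x$n_res,
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  final backbone RMSD: %.2f A; final whole-protein Q: %.3f\n",
              utils::tail(x$rmsd$value, 1), utils::tail(x$q_whole$value, 1)))
  if (!is.null(x$events) && nrow(x$events)) {
    cat(sprintf("  %d beta-loss event(s), first: %s at %.4g ns\n",
                nrow(x$events), x$events$region[1], x$events$onset_ns[1]))
  } else cat("  no beta-loss events detected\n")
  if (!is.null(x$motion) && !is.na(x$motion$fraction_closure))
    cat(sprintf("  interdomain motion: %.1f%% closure / %.1f%% twist\n",
                x$motion$fraction_closure, x$motion$fraction_twist))
  invisible(x)
}

#' @export
summary.unfolding_analysis <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$pca)) {
    tot <- max(x$pca$trace, .Machine$double.eps)
    cat(sprintf("  essential dynamics: lambda1 %.3g A^2 (%.1f%%), lambda2 %.3g A^2 (%.1f%%)\n",
                x$pca$values[1], 100 * x$pca$values[1] / tot,
                x$pca$values[2], 100 * x$pca$values[2] / tot))
  }
  if (!is.null(x$events) && nrow(x$events)) {
    cat("  event sequence:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("    %d. %-18s %7.4g ns  %s (beta %.0f%% -> %.0f%%)\n", i,
                  x$events$region[i], x$events$onset_ns[i], x$events$kind[i],
                  x$events$beta_before_pct[i], x$events$beta_after_pct[i]))
  }
  if (!is.null(x$aromatic_persistence)) {
    top <- x$aromatic_persistence[order(-x$aromatic_persistence$persistence_pct), ]
    top <- utils::head(top, 5)
    cat("  most persistent aromatic pairs (%):\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %d-%d: %.1f\n", top$res_a[i], top$res_b[i],
                  top$persistence_pct[i]))
  }
  if (!is.null(x$cluster_events) && nrow(x$cluster_events))
    cat(sprintf("  new aromatic cluster(s): %s (onset %.4g ns)\n",
                paste(x$cluster_events$members, collapse = "; "),
                x$cluster_events$onset_ns[1]))
  invisible(x)
}

#' @export
plot.unfolding_analysis <- function(x, which = c("q", "rmsd", "rmsf", "pca"),
                                    ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (w in which) {
    if (w == "q") {
      plot(x$q_whole$time_ns, x$q_whole$value, type = "l",
           xlab = "time (ns)", ylab = "Q", main = "contact fraction",
           ylim = c(0, max(1, x$q_whole$value)))
      cols <- grDevices::rainbow(length(x$q_regions))
      for (i in seq_along(x$q_regions))
        graphics::lines(x$q_regions[[i]]$time_ns, x$q_regions[[i]]$value,
                        col = cols[i], lty = 2)
    } else if (w == "rmsd") {
      plot(x$rmsd$time_ns, x$rmsd$value, type = "l", xlab = "time (ns)",
           ylab = "RMSD (A)", main = "backbone RMSD")
    } else if (w == "rmsf" && !is.null(x$rmsf)) {
      plot(x$rmsf$resno, x$rmsf$rmsf, type = "h", xlab = "residue",
           ylab = "RMSF (A)", main = "per-residue RMSF")
    } else if (w == "pca" && !is.null(x$projections)) {
      plot(x$projections$pc1, x$projections$pc2, pch = 16, cex = 0.6,
           col = grDevices::hcl.colors(nrow(x$projections), "viridis"),
           xlab = "PC1", ylab = "PC2", main = "essential dynamics")
    }
  }
  invisible(x)
}

# ---- TSV / report plumbing ------------------------------------------------------

.write_tsv <- function(df, path, header_params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_params))
    writeLines(paste0("# ", paste(names(header_params), unlist(header_params),
                                  sep = "=", collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_matrix_tsv <- function(m, path, header_params = NULL, rownames_col = "residue") {
  df <- data.frame(rownames_col = seq_len(nrow(m)), unclass(m),
                   check.names = FALSE)
  names(df) <- c(rownames_col, paste0("r", seq_len(ncol(m))))
  .write_tsv(df, path, header_params)
}

#' Read a key-value config file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#'
#' @param path config file path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("cannot parse config line: ", ln)
    out[[trimws(kv[1])]] <- trimws(gsub('"', "", paste(kv[-1], collapse = "=")))
  }
  out
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates, in order: RMSD/RMSF, PCA projections, Q series (whole and
#' per region), ensemble contact map, secondary-structure matrix and ordered
#' unfolding events, aromatic persistence and cluster formation, and motion
#' fractions. All tables are written as TSV with a one-line `#` parameter
#' header, plus a JSON manifest with md5 checksums so reruns are verifiable.
#'
#' @param config named list (or path to a key-value config file) with entries:
#'   `traj` (multi-model PDB path) or `analysis_input` (an `mdu_trajectory`),
#'   optional `regions` (config path; default built-in map), `dt` (ns/frame),
#'   `out_dir` (required), and optional `stride`, `cutoff`, `band_low`,
#'   `band_high`, `ss_threshold`, `ss_persistence`, `fixed_domain`,
#'   `moving_domain`, `seed`.
#' @return A list of class `mdu_report`: `manifest` (data frame: name, path,
#'   md5), `analysis` (the `unfolding_analysis` object), `params`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  num <- function(key, default) if (is.null(config[[key]])) default else
    as.numeric(config[[key]])
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t0 <- Sys.time()
  if (!is.null(config$analysis_input)) {
    traj <- config$analysis_input
  } else {
    if (is.null(config$traj)) stop("config must name a trajectory (traj=...)")
    traj <- read_trajectory(config$traj, dt = num("dt", 0.25))
  }
  regions <- if (!is.null(config$regions_map)) config$regions_map else
    load_regions(config$regions)

  params <- list(stride = as.integer(num("stride", 1)),
                 cutoff = num("cutoff", 6.5),
                 min_separation = as.integer(num("min_separation", 1)),
                 band = c(num("band_low", 4.5), num("band_high", 7.0)),
                 ss_threshold = num("ss_threshold", 50),
                 ss_persistence = as.integer(num("ss_persistence", 5)),
                 ss_window = as.integer(num("ss_window", 5)),
                 seed = as.integer(num("seed", 1)))
  hdr <- params; hdr$band <- paste(params$band, collapse = ":")

  an <- unfolding_analysis(traj, regions, stride = params$stride,
                           cutoff = params$cutoff,
                           min_separation = params$min_separation,
                           band = params$band,
                           ss_threshold = params$ss_threshold,
                           ss_persistence = params$ss_persistence,
                           ss_window = params$ss_window,
                           fixed_domain = config$fixed_domain,
                           moving_domain = config$moving_domain)

  files <- character()
  put <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    files[[length(files) + 1L]] <<- p
    names(files)[length(files)] <<- name
    p
  }
  put("rmsd.tsv", function(p) .write_tsv(
    data.frame(time_ns = an$rmsd$time_ns, rmsd_A = an$rmsd$value), p, hdr))
  if (!is.null(an$rmsf)) put("rmsf.tsv", function(p) .write_tsv(
    data.frame(residue = an$rmsf$resno, rmsf_A = an$rmsf$rmsf), p, hdr))
  if (!is.null(an$projections)) put("pca_projections.tsv", function(p)
    .write_tsv(an$projections, p, hdr))
  q_long <- data.frame(time_ns = an$q_whole$time_ns, Q = an$q_whole$value,
                       scope = "whole")
  for (r in names(an$q_regions))
    q_long <- rbind(q_long, data.frame(time_ns = an$q_regions[[r]]$time_ns,
                                       Q = an$q_regions[[r]]$value, scope = r))
  put("q_series.tsv", function(p) .write_tsv(q_long, p, hdr))
  put("contact_map.tsv", function(p) .write_matrix_tsv(an$contact_map, p, hdr))
  put("ss_matrix.tsv", function(p) {
    m <- unclass(an$ss)
    df <- data.frame(residue = attr(an$ss, "resno"), m)
    names(df) <- c("residue", sprintf("t%g", attr(an$ss, "times")))
    .write_tsv(df, p, hdr)
  })
  put("events.tsv", function(p) .write_tsv(an$events, p, hdr))
  if (!is.null(an$aromatic_persistence)) {
    put("persistence.tsv", function(p) .write_tsv(an$aromatic_persistence, p, hdr))
    put("clusters.tsv", function(p) .write_tsv(an$cluster_events, p, hdr))
  }
  if (!is.null(an$motion)) put("motion.tsv", function(p)
    .write_tsv(an$motion$frames, p, hdr))

  manifest <- data.frame(name = names(files), path = unname(files),
                         md5 = unname(tools::md5sum(unname(files))),
                         stringsAsFactors = FALSE)
  meta <- list(parameters = hdr,
               package_version = as.character(utils::packageVersion("mdunfold")),
               n_frames = length(traj$times), n_residues = n_residues(traj$topology),
               wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               tables = manifest)
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(manifest = manifest, analysis = an, params = params,
                 out_dir = out_dir), class = "mdu_report")
}

#' @export
print.mdu_report <- function(x, ...) {
  cat(sprintf("<mdu_report> %d table(s) in %s\n", nrow(x$manifest), x$out_dir))
  print(x$manifest[, c("name", "md5")], row.names = FALSE)
  invisible(x)
}

#' Compare two trajectory ensembles by subtractive contact map
#'
#' Emits the subtractive contact map of two analyses in both modes (`raw`:
#' difference of ensemble frequencies; `loss`: difference of per-ensemble
#' change maps) plus mean contact frequencies over configured region pairs.
#'
#' @param analysis_a,analysis_b `unfolding_analysis` objects sharing topology
#'   dimensions. Negative entries mark contacts whose loss is greater in A.
#' @param region_pairs optional list of `c(region_a, region_b)` name pairs
#'   summarized from both maps.
#' @param topology,regions needed when `region_pairs` is given.
#' @param out_dir optional directory to write `subtractive_raw.tsv`,
#'   `subtractive_loss.tsv` and `region_pair_summary.tsv` into.
#' @return List with `raw`, `loss` (signed matrices) and `summaries`
#'   (data frame or NULL).
#' @export
compare_trajectories <- function(analysis_a, analysis_b, region_pairs = NULL,
                                 topology = NULL, regions = NULL,
                                 out_dir = NULL) {
  ma <- analysis_a$contact_map; mb <- analysis_b$contact_map
  raw <- subtractive_map(ma, mb, "raw")
  loss <- subtractive_map(ma, mb, "loss")
  summaries <- NULL
  if (!is.null(region_pairs)) {
    if (is.null(topology) || is.null(regions))
      stop("topology and regions are required for region-pair summaries")
    rows <- lapply(region_pairs, function(rp) data.frame(
      region_a = rp[1], region_b = rp[2],
      mean_freq_A = region_pair_contact_summary(ma, topology, rp[1], rp[2], regions),
      mean_freq_B = region_pair_contact_summary(mb, topology, rp[1], rp[2], regions),
      stringsAsFactors = FALSE))
    summaries <- do.call(rbind, rows)
    summaries$difference <- summaries$mean_freq_A - summaries$mean_freq_B
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_matrix_tsv(raw, file.path(out_dir, "subtractive_raw.tsv"))
    .write_matrix_tsv(loss, file.path(out_dir, "subtractive_loss.tsv"))
    if (!is.null(summaries))
      .write_tsv(summaries, file.path(out_dir, "region_pair_summary.tsv"))
  }
  list(raw = raw, loss = loss, summaries = summaries)
}
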