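# Noise-robustness simulation: planar Gaussian blobs, Gaussian
# perturbation of the pairwise distances, and a multi-method sweep
# recording cluster counts and incorrect pairs per replicate.

#' Configuration for the distance-noise experiment
#'
#' Defaults reproduce the study conditions: 80 points around four
#' centres `(0,8)`, `(0,-8)`, `(8,0)`, `(-8,0)` (20 per centre, N(0,1)
#' offsets in x and y), Euclidean distances perturbed per unordered pair
#' with N(0, sd^2) noise over a grid of perturbation SDs, 100 replicate
#' perturbations per SD, and SCG compared against complete, average and
#' single linkage at distance cutoffs 2 and 4.
#'
#' @param centers Numeric matrix of blob centres (one row per centre).
#' @param points_per_center Points drawn around each centre.
#' @param point_noise_sd SD of the x/y offsets around each centre.
#' @param sd_grid Perturbation SDs to sweep.
#' @param replicates Replicate perturbations per SD.
#' @param cutoffs Distance cutoffs for the linkage baselines.
#' @param methods Methods to run: subset of `"scg"`, `"cl"`, `"al"`,
#'   `"sl"`.
#' @param redraw_points If `FALSE` (default) one point set is generated
#'   and only the perturbation is redrawn per replicate; if `TRUE` the
#'   points are redrawn each replicate as well.
#' @param seed Master seed; every run with the same config is
#'   reproducible.
#' @return A list of class `scg_noise_config`.
#' @export
noise_experiment_config <- function(centers = rbind(c(0, 8), c(0, -8),
                                                    c(8, 0), c(-8, 0)),
                                    points_per_center = 20L,
                                    point_noise_sd = 1,
                                    sd_grid = seq(0, 3, by = 0.25),
                                    replicates = 100L,
                                    cutoffs = c(2, 4),
                                    methods = c("scg", "cl", "al", "sl"),
                                    redraw_points = FALSE,
                                    seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is.matrix(centers), ncol(centers) == 2, nrow(centers) >= 1,
            points_per_center >= 1L, point_noise_sd >= 0,
            all(sd_grid >= 0), replicates >= 1L, all(cutoffs > 0))
  structure(
    list(centers = centers, points_per_center = as.integer(points_per_center),
         point_noise_sd = point_noise_sd, sd_grid = sd_grid,
         replicates = as.integer(replicates), cutoffs = cutoffs,
         methods = methods, redraw_points = isTRUE(redraw_points),
         seed = as.integer(seed)),
    class = "scg_noise_config"
  )
}

#' Generate planar Gaussian-blob points with their reference partition
#'
#' Draws `points_per_center` points around each centre, offsetting both
#' coordinates independently by N(0, sd^2) noise. The reference
#' partition groups points by their generating centre.
#'
#' @param config An [noise_experiment_config()] (only the point-related
#'   fields are used).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return List with `points` (n x 2 matrix, labelled `p1..pn`) and
#'   `reference` (named integer partition).
#' @export
generate_blob_points <- function(config = noise_experiment_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(config$centers)
  per <- config$points_per_center
  n <- k * per
  pts <- matrix(0, n, 2)
  ref <- integer(n)
  for (c in seq_len(k)) {
    idx <- ((c - 1L) * per + 1L):(c * per)
    pts[idx, 1] <- config$centers[c, 1] +
      stats::rnorm(per, 0, config$point_noise_sd)
    pts[idx, 2] <- config$centers[c, 2] +
      stats::rnorm(per, 0, config$point_noise_sd)
    ref[idx] <- c
  }
  labels <- paste0("p", seq_len(n))
  rownames(pts) <- labels
  names(ref) <- labels
  list(points = pts, reference = ref)
}

#' Perturb a distance matrix with Gaussian noise
#'
#' Adds one N(0, sd^2) draw per unordered pair, applied to both
#' orientations so the matrix stays symmetric. The diagonal is left
#' untouched and `sd = 0` returns the input unchanged. Perturbed
#' distances may go negative; this is deliberate, since the rank
#' transform depends only on the ordering and clamping would manufacture
#' ties.
#'
#' @param D Symmetric numeric distance matrix.
#' @param sd Perturbation standard deviation (>= 0).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Perturbed symmetric matrix of the same shape.
#' @export
perturb_distances <- function(D, sd, seed = NULL) {
  if (sd < 0) stop("`sd` must be non-negative")
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (ncol(D) != n) stop("distance matrix must be square")
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(D)
  noise <- matrix(0, n, n)
  up <- upper.tri(noise)
  noise[up] <- stats::rnorm(sum(up), 0, sd)
  noise <- noise + t(noise)
  D + noise
}

#' Run the distance-noise experiment
#'
#' For every perturbation SD and replicate, perturbs the pairwise
#' Euclidean distances of the blob dataset, runs every configured method
#' and records the number of clusters (independent clusters including
#' singletons for SCG; flat groups including singletons for the linkage
#' baselines at each cutoff) and the number of incorrect pairs against
#' the generating-centre reference. SCG is run as SCG-fast ([scg_a2()]),
#' which suffices because only the independent clusters are counted.
#'
#' @param config An [noise_experiment_config()].
#' @return Object of class `scg_noise_experiment`: list with
#'   `replicates` (one row per method x cutoff x SD x replicate) and
#'   `summary` (mean and SD over replicates of both statistics), plus
#'   the `config`.
#' @export
run_noise_experiment <- function(config = noise_experiment_config()) {
  stopifnot(inherits(config, "scg_noise_config"))
  set.seed(config$seed)
  data <- if (config$redraw_points) NULL else generate_blob_points(config)

  method_specs <- list()
  for (m in config$methods) {
    if (m == "scg") {
      method_specs[[length(method_specs) + 1L]] <-
        list(method = "scg", cutoff = NA_real_)
    } else {
      for (cf in config$cutoffs) {
        method_specs[[length(method_specs) + 1L]] <-
          list(method = m, cutoff = cf)
      }
    }
  }
  linkage_name <- c(cl = "complete", al = "average", sl = "single")

  rows <- vector("list",
                 length(config$sd_grid) * config$replicates *
                   length(method_specs))
  r <- 0L
  for (sd in config$sd_grid) {
    for (rep in seq_len(config$replicates)) {
      if (config$redraw_points) data <- generate_blob_points(config)
      D0 <- as.matrix(stats::dist(data$points))
      D <- perturb_distances(D0, sd)
      partitions <- list()
      for (spec in method_specs) {
        key <- paste(spec$method, spec$cutoff)
        if (spec$method == "scg") {
          rm <- scg_rank_matrix(D)
          part <- independent_clusters(scg_a2(rm))
        } else {
          part <- linkage_partition(D, linkage_name[[spec$method]],
                                    cutoff = spec$cutoff)
        }
        pe <- count_pair_errors(part, data$reference)
        r <- r + 1L
        rows[[r]] <- data.frame(
          method = spec$method, cutoff = spec$cutoff, sd = sd,
          replicate = rep,
          n_clusters = length(unique(part)),
          incorrect_pairs = pe$incorrect
        )
      }
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(n_clusters, incorrect_pairs) ~ method + cutoff + sd,
    data = transform(replicates,
                     cutoff = ifelse(is.na(cutoff), -1, cutoff)),
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x)),
    na.action = stats::na.pass
  )
  summary <- data.frame(
    method = summary$method,
    cutoff = ifelse(summary$cutoff < 0, NA, summary$cutoff),
    sd = summary$sd,
    n_clusters_mean = summary$n_clusters[, "mean"],
    n_clusters_sd = summary$n_clusters[, "sd"],
    incorrect_pairs_mean = summary$incorrect_pairs[, "mean"],
    incorrect_pairs_sd = summary$incorrect_pairs[, "sd"]
  )
  summary <- summary[order(summary$method, summary$cutoff, summary$sd), ]
  rownames(summary) <- NULL
  structure(list(replicates = replicates, summary = summary,
                 config = config),
            class = "scg_noise_experiment")
}

#' @export
print.scg_noise_experiment <- function(x, ...) {
  cat("Distance-noise experiment:", nrow(x$replicates),
      "replicate records over", length(x$config$sd_grid),
      "perturbation SDs\n")
  print(utils::head(x$summary, 12))
  invisible(x)
}
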