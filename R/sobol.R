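#' Parameter box for sensitivity analysis
#'
#' A parameter box is an ordered set of model parameters with lower and
#' upper bounds and a unit tag.  [sensitivity_box()] returns the 11-parameter
#' box used for the global sensitivity analysis of the twitching model:
#' spawn rate and dwell-time bounds follow recent single-pilus
#' experiments, the motor rates span roughly their reported 95%
#' confidence intervals, and the remaining parameters are varied by at
#' least an order of magnitude around their estimates.  Retraction-speed
#' bounds are stored in um/s (0.0025--0.25, i.e. 2.5--250 nm/s).
#'
#' @param name Character vector of parameter names (must be
#'   [sim_params()] fields).
#' @param min,max Numeric bounds, `min < max` elementwise.
#' @param unit Character unit tags (documentation only).
#' @return A data frame of class `parameter_box`.
#' @export
parameter_box <- function(name, min, max, unit = "") {
  stopifnot(length(name) == length(min), length(min) == length(max),
            all(min < max))
  bad <- setdiff(name, setdiff(names(sim_params()), c("surface", "mode")))
  if (length(bad)) stop("not sim_params fields: ", paste(bad, collapse = ", "))
  structure(data.frame(name = name, min = min, max = max,
                       unit = rep_len(unit, length(name)),
                       stringsAsFactors = FALSE),
            class = c("parameter_box", "data.frame"))
}

#' @rdname parameter_box
#' @export
sensitivity_box <- function() {
  parameter_box(
    name = c("k_ext_off", "tau_dwell", "kappa", "v_ret", "k_spawn",
             "k_ext_on", "k_resample", "k_ret_off", "L_p", "E", "f_stall"),
    min = c(0.2, 0.5, 1, 0.0025, 0.1, 0.2, 0.5, 0.05, 1, 1000, 20),
    max = c(1, 3, 15, 0.25, 8, 0.5, 10, 0.2, 10, 20000, 200),
    unit = c("1/s", "s", "", "um/s", "1/s", "1/s", "1/s", "1/s",
             "um", "pN/um", "pN"))
}

# Radical-inverse (van der Corput) sequence in the given base.
.radical_inverse <- function(idx, base) {
  out <- numeric(length(idx))
  f <- 1 / base
  i <- idx
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

# Randomised Halton points in [0,1)^dim: digit sequence per prime base
# plus a uniform random shift (Cranley-Patterson rotation).
.halton <- function(n, dim, shift = NULL) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101)
  if (dim > length(primes)) stop("dimension too large for the Halton bases")
  if (is.null(shift)) shift <- runif(dim)
  idx <- seq_len(n) + 20L # drop the first points (origin-heavy)
  m <- vapply(seq_len(dim),
              function(j) (.radical_inverse(idx, primes[j]) + shift[j]) %% 1,
              numeric(n))
  matrix(m, nrow = n)
}

#' Saltelli sampling design for total-effect indices
#'
#' Builds the A, B and A_B^(i) blocks of the Saltelli scheme from a
#' randomised low-discrepancy (Halton) sequence: `n_base` rows for each of
#' A and B, plus one block per parameter in which column i of A is
#' replaced by column i of B, for `n_base * (d + 2)` model evaluations in
#' total.
#'
#' @param box A [parameter_box()].
#' @param n_base Base sample size (a power of two keeps the sequence
#'   well balanced).
#' @param seed Integer seed for the randomising shift.
#' @return A list of class `saltelli_design` with elements `design` (the
#'   full `n_base * (d + 2)` by `d` matrix, rows ordered A, B, AB_1 ..
#'   AB_d), `n_base`, `box` and `block` (a factor labelling rows).
#' @examples
#' d <- saltelli_design(sensitivity_box(), n_base = 4, seed = 1)
#' nrow(d$design) # 4 * (11 + 2)
#' @export
saltelli_design <- function(box, n_base, seed = NULL) {
  stopifnot(inherits(box, "parameter_box"), n_base >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- nrow(box)
  H <- .halton(n_base, 2 * d)
  A <- H[, seq_len(d), drop = FALSE]
  B <- H[, d + seq_len(d), drop = FALSE]
  scale_row <- function(M) {
    t(box$min + t(M) * (box$max - box$min))
  }
  blocks <- vector("list", d + 2)
  blocks[[1]] <- A
  blocks[[2]] <- B
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    blocks[[i + 2]] <- ABi
  }
  design <- scale_row(do.call(rbind, blocks))
  colnames(design) <- box$name
  block <- factor(rep(c("A", "B", paste0("AB_", box$name)),
                      each = n_base),
                  levels = c("A", "B", paste0("AB_", box$name)))
  structure(list(design = design, n_base = n_base, box = box,
                 block = block),
            class = "saltelli_design")
}

#' Sobol total-effect indices (Jansen estimator)
#'
#' Estimates the total-effect index of each parameter,
#' S_T,i = E_x~i\[Var_xi(f)\] / Var(f), from aligned model evaluations of
#' the Saltelli blocks using the Jansen estimator
#' S_T,i = mean((f_A - f_AB_i)^2) / (2 Var(f)), clipped to \[0, 1\], with
#' a bootstrap confidence interval over design rows.
#'
#' @param f_A,f_B Model evaluations on the A and B blocks (length n).
#' @param f_AB An n x d matrix of evaluations on the AB_i blocks.
#' @param n_boot Bootstrap replicates for the confidence intervals.
#' @param conf Confidence level.
#' @return A data frame with `S_T` (clipped to \[0, 1\]), the unclipped
#'   `S_T_raw` (rank comparisons among noisy saturated estimates need the
#'   unclipped values), `ci_lo`, `ci_hi` per parameter (rownames from
#'   `colnames(f_AB)`); attribute `var_f` holds the output variance.  All-NA with a warning when the output variance is
#'   (numerically) zero.
#' @examples
#' # S_T = (1, 0) for f(x) = x1 on the unit box
#' n <- 256; A <- matrix(runif(2 * n), n); B <- matrix(runif(2 * n), n)
#' total_effect(A[, 1], B[, 1], cbind(B[, 1], A[, 1]))
#' @export
total_effect <- function(f_A, f_B, f_AB, n_boot = 200, conf = 0.95) {
  f_AB <- as.matrix(f_AB)
  n <- length(f_A)
  stopifnot(length(f_B) == n, nrow(f_AB) == n)
  var_f <- stats::var(c(f_A, f_B))
  d <- ncol(f_AB)
  if (!is.finite(var_f) || var_f < 1e-12 * (mean(c(f_A, f_B))^2 + 1e-12)) {
    warning("degenerate output: variance is (numerically) zero; S_T undefined")
    out <- data.frame(S_T = rep(NA_real_, d), ci_lo = NA_real_,
                      ci_hi = NA_real_)
    rownames(out) <- colnames(f_AB)
    attr(out, "var_f") <- var_f
    return(out)
  }
  jansen <- function(idx) {
    v <- stats::var(c(f_A[idx], f_B[idx]))
    colMeans((f_A[idx] - f_AB[idx, , drop = FALSE])^2) / (2 * v)
  }
  raw <- jansen(seq_len(n))
  S_T <- pmin(pmax(raw, 0), 1)
  boot <- replicate(n_boot, pmin(pmax(jansen(
    sample.int(n, n, replace = TRUE)), 0), 1))
  if (d == 1) boot <- matrix(boot, nrow = 1)
  alpha <- (1 - conf) / 2
  out <- data.frame(S_T = S_T, S_T_raw = raw,
                    ci_lo = apply(boot, 1, stats::quantile, alpha),
                    ci_hi = apply(boot, 1, stats::quantile, 1 - alpha))
  rownames(out) <- colnames(f_AB)
  attr(out, "var_f") <- var_f
  out
}

#' Global sensitivity analysis of the twitching model
#'
#' Simulates one trajectory per design row of a [saltelli_design()] and
#' reduces it to the four summary statistics of [summary_stats()], then
#' estimates the Sobol total-effect index of every parameter for every
#' statistic.  Rows whose trajectory is too immotile to yield three
#' linearised steps have undefined persistence statistics; they are
#' imputed with the immobile-limit floor (zero persistence, activity and
#' deviation-angle variance) and counted in the result, so that
#' mobility itself stays part of the measured response.
#'
#' @param box A [parameter_box()], typically [sensitivity_box()].
#' @param n_base Saltelli base sample size; the run simulates
#'   `n_base * (d + 2)` trajectories.
#' @param duration Simulated seconds per design point.
#' @param base_params Baseline [sim_params()] the design rows overwrite.
#' @param mode Simulation mode for all rows.
#' @param seed Master seed (design randomisation and per-row streams).
#' @param delta_step Linearisation step (um).
#' @param trim Velocity trim fraction passed to [summary_stats()].
#' @param n_boot Bootstrap replicates for the index confidence intervals.
#' @param rank_transform Estimate the indices on rank-transformed
#'   statistics.  The raw trajectory statistics are heavy-tailed at small
#'   per-row simulation budgets, which destabilises variance-based
#'   estimators; the rank transformation (a standard robustification for
#'   non-normal outputs) preserves the dominance ordering of monotone
#'   effects and makes the index ranking reproducible at desk scale.
#' @param progress Print a dot every 50 rows.
#' @return An object of class `sobol_result`: list with `indices` (array
#'   parameter x statistic of S_T), `ci_lo`/`ci_hi`, `max_S_T` (rowwise
#'   max over statistics), `stats` (the raw per-row statistics), `design`,
#'   `n_imputed`, `n_base`.
#' @export
run_sensitivity <- function(box = sensitivity_box(), n_base = 128,
                            duration = 2000,
                            base_params = sim_params(mode = "crawling"),
                            mode = "crawling", seed = 1,
                            delta_step = 0.12, trim = 0.01,
                            n_boot = 200, rank_transform = FALSE,
                            progress = FALSE) {
  des <- saltelli_design(box, n_base, seed = seed)
  D <- des$design
  nrows <- nrow(D)
  set.seed(as.integer(seed) + 1L)
  row_seeds <- sample.int(.Machine$integer.max - 1L, nrows)
  stat_names <- c("mean_speed", "var_dev", "q_hat", "a_hat")
  S <- matrix(NA_real_, nrows, 4, dimnames = list(NULL, stat_names))
  eval_row <- function(i, sd) {
    p <- do.call(update_params,
                 c(list(base_params), as.list(D[i, ])))
    p$mode <- mode
    sim <- suppressWarnings(simulate_twitching(p, duration = duration,
                                               seed = sd))
    s <- summary_stats(linearise(sim, delta_step = delta_step), trim = trim)
    stats_vector(s)
  }
  for (i in seq_len(nrows)) {
    S[i, ] <- eval_row(i, row_seeds[i])
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  # immotile rows (< 3 linearised steps) have undefined persistence
  # statistics; impute the immobile-limit floor
  n_imputed <- sum(is.na(S))
  S[is.na(S[, "mean_speed"]), "mean_speed"] <- 0
  for (j in c("var_dev", "q_hat", "a_hat")) S[is.na(S[, j]), j] <- 0
  Suse <- if (rank_transform) apply(S, 2, rank, ties.method = "average")
          else S
  d <- nrow(box)
  iA <- seq_len(n_base)
  iB <- n_base + iA
  indices <- raw <- ci_lo <- ci_hi <-
    matrix(NA_real_, d, 4, dimnames = list(box$name, stat_names))
  for (j in seq_len(4)) {
    f_AB <- vapply(seq_len(d),
                   function(k) Suse[(k + 1) * n_base + iA, j],
                   numeric(n_base))
    te <- total_effect(Suse[iA, j], Suse[iB, j], f_AB, n_boot = n_boot)
    indices[, j] <- te$S_T
    raw[, j] <- te$S_T_raw
    ci_lo[, j] <- te$ci_lo
    ci_hi[, j] <- te$ci_hi
  }
  structure(list(indices = indices, indices_raw = raw,
                 ci_lo = ci_lo, ci_hi = ci_hi,
                 max_S_T = apply(indices, 1, max),
                 stats = S, design = des, n_imputed = n_imputed,
                 n_base = n_base),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, digits = 3, ...) {
  cat("<sobol_result> total-effect indices (n_base =", x$n_base, ")\n")
  tab <- cbind(round(x$indices, digits), max_S_T = round(x$max_S_T, digits))
  print(tab)
  if (x$n_imputed > 0)
    cat("  (", x$n_imputed, "undefined statistics imputed )\n")
  invisible(x)
}
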