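#' AFM tip specification (four-sided pyramidal indenter)
#'
#' @param half_angle face half-angle alpha of the pyramid in degrees,
#'   in (0, 90).
#' @param spring_constant cantilever spring constant in N/m (> 0);
#'   metadata only, deflection conversion is out of scope.
#' @param poisson_ratio sample Poisson ratio; 0.5 (incompressible) is the
#'   usual choice for cells.
#' @return An object of class `tip_spec`.
#' @export
tip_spec <- function(half_angle = 35, spring_constant = 0.01,
                     poisson_ratio = 0.5) {
  stopifnot(half_angle > 0, half_angle < 90, spring_constant > 0,
            poisson_ratio >= 0, poisson_ratio < 0.51)
  structure(list(half_angle = half_angle, spring_constant = spring_constant,
                 poisson_ratio = poisson_ratio), class = "tip_spec")
}

# pyramid contact prefactor: F[nN] = hertz_prefactor(tip) * E[Pa] * (delta[µm])^2
# (Pa * µm^2 = 1e-12 N = 1e-3 nN)
hertz_prefactor <- function(tip) {
  tan(tip$half_angle * pi / 180) / (sqrt(2) * (1 - tip$poisson_ratio^2)) * 1e-3
}

#' Generate a synthetic AFM force-indentation curve
#'
#' Evaluates the pyramidal-tip contact law
#' \deqn{F(\delta) = \frac{\tan\alpha}{\sqrt 2 (1-\nu^2)} E (\delta-\delta_0)^2}
#' for \eqn{\delta > \delta_0} (0 before contact) on a uniform indentation
#' grid and adds Gaussian force noise.
#'
#' @param E Young's modulus in Pa (>= 0).
#' @param tip a [tip_spec].
#' @param max_indentation maximum indentation in µm (> 0).
#' @param n_points number of grid points.
#' @param noise_sd Gaussian force noise sd in nN.
#' @param contact_offset true contact point \eqn{\delta_0} in µm.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return A data.frame of class `force_curve` with columns `indentation`
#'   (µm) and `force` (nN).
#' @export
generate_force_curve <- function(E, tip = tip_spec(), max_indentation = 1,
                                 n_points = 200L, noise_sd = 0,
                                 contact_offset = 0, seed = 1L) {
  stopifnot(E >= 0, max_indentation > 0, n_points >= 2L, noise_sd >= 0)
  delta <- seq(0, max_indentation, length.out = n_points)
  f <- hertz_prefactor(tip) * E * pmax(delta - contact_offset, 0)^2
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(n_points, 0, noise_sd)
  }
  structure(data.frame(indentation = delta, force = f),
            class = c("force_curve", "data.frame"))
}

#' Fit the pyramidal Hertz model to a force-indentation curve
#'
#' Least-squares fit of
#' \eqn{F = \frac{\tan\alpha}{\sqrt 2(1-\nu^2)} E (\delta-\delta_0)^2}
#' for \eqn{\delta > \delta_0}, jointly over the modulus `E >= 0` and the
#' contact offset \eqn{\delta_0}. For a fixed offset the optimal modulus is
#' available in closed form, so the fit profiles the residual sum of squares
#' over the offset (grid search refined by golden-section optimization).
#'
#' @param curve a `force_curve` data.frame (columns `indentation`, `force`)
#'   with non-decreasing indentation and at least 10 points past contact.
#' @param tip a [tip_spec].
#' @return A list of class `hertz_fit` with `E` (Pa), `contact_offset`
#'   (µm), `residual_rms` (nN) and `degenerate` (all-zero force input).
#' @export
fit_hertz <- function(curve, tip = tip_spec()) {
  stopifnot(is.data.frame(curve),
            all(c("indentation", "force") %in% names(curve)))
  delta <- curve$indentation
  f <- curve$force
  if (any(!is.finite(delta)) || any(!is.finite(f)))
    stop("force curve contains non-finite values")
  if (is.unsorted(delta)) stop("indentation must be non-decreasing")
  if (max(abs(f)) == 0) {
    return(structure(list(E = 0, contact_offset = 0, residual_rms = 0,
                          degenerate = TRUE), class = "hertz_fit"))
  }
  c0 <- hertz_prefactor(tip)
  n <- length(delta)
  rss_E <- function(d0) {
    g <- c0 * pmax(delta - d0, 0)^2
    sg2 <- sum(g^2)
    if (sg2 == 0 || sum(delta > d0) < 10L) return(c(sum(f^2), 0))
    E <- max(0, sum(f * g) / sg2)
    c(sum((f - E * g)^2), E)
  }
  # profile over the contact offset: coarse grid, then local refinement
  hi <- delta[n] - (delta[n] - delta[1]) * 0.2
  grid <- seq(delta[1] - (delta[n] - delta[1]) * 0.1, hi, length.out = 101L)
  rss <- vapply(grid, function(d) rss_E(d)[1], numeric(1))
  i <- which.min(rss)
  lo_b <- grid[max(1L, i - 1L)]
  hi_b <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(d) rss_E(d)[1], c(lo_b, hi_b),
                         tol = 1e-10)
  d0 <- opt$minimum
  res <- rss_E(d0)
  # keep the grid minimum if refinement did not help
  if (rss[i] < res[1]) { d0 <- grid[i]; res <- rss_E(d0) }
  structure(list(E = res[2], contact_offset = d0,
                 residual_rms = sqrt(res[1] / n), degenerate = FALSE),
            class = "hertz_fit")
}

#' Generate a synthetic qPCR Ct table
#'
#' Builds Ct values for a two-group design (control vs treated) such that
#' noiseless delta-delta-Ct recovery returns the requested fold changes
#' exactly: treated-group target Ct values are shifted by `-log2(fold)`
#' relative to the control delta-Ct.
#'
#' @param true_folds named numeric vector of per-gene fold changes (> 0),
#'   treated relative to control.
#' @param n_replicates samples per group.
#' @param ct_noise_sd Gaussian noise sd added to every Ct value (cycles).
#' @param reference_gene reference (housekeeping) gene name.
#' @param groups names of the control and treated group.
#' @param seed RNG seed.
#' @return A data.frame of class `ct_table` with columns `sample`, `group`,
#'   `gene`, `ct`; attribute `reference_gene`.
#' @export
generate_ct_table <- function(true_folds, n_replicates = 3L, ct_noise_sd = 0,
                              reference_gene = "GAPDH",
                              groups = c("control", "treated"), seed = 1L) {
  stopifnot(length(true_folds) >= 1L, all(true_folds > 0),
            !is.null(names(true_folds)), length(groups) == 2L,
            n_replicates >= 1L, ct_noise_sd >= 0)
  set.seed(seed)
  base_ref <- 20
  base_dct <- 5  # control-group delta-Ct per target gene
  rows <- list()
  for (g in seq_along(groups)) {
    for (s in seq_len(n_replicates)) {
      sample_id <- sprintf("%s_%d", groups[g], s)
      ref_ct <- base_ref + (g - 1) * 0.5
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, group = groups[g], gene = reference_gene,
        ct = ref_ct, stringsAsFactors = FALSE)
      for (gene in names(true_folds)) {
        dct <- base_dct - if (g == 2L) log2(true_folds[[gene]]) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, group = groups[g], gene = gene,
          ct = ref_ct + dct, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (ct_noise_sd > 0) out$ct <- out$ct + stats::rnorm(nrow(out), 0, ct_noise_sd)
  attr(out, "reference_gene") <- reference_gene
  class(out) <- c("ct_table", class(out))
  out
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Per sample, \eqn{\Delta Ct = Ct_{target} - Ct_{ref}}; per gene and group,
#' \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{group} -
#' \overline{\Delta Ct}_{control}}; the fold change is
#' \eqn{2^{-\Delta\Delta Ct}}. The control group fold is 1 by construction.
#'
#' @param cts a Ct table data.frame with columns `sample`, `group`, `gene`,
#'   `ct`.
#' @param control_group name of the control group.
#' @param reference_gene reference gene name; defaults to the table's
#'   `reference_gene` attribute, else `"GAPDH"`.
#' @return data.frame with columns `gene`, `group`, `delta_ct_mean`,
#'   `ddct`, `fold`.
#' @export
ddct_fold_change <- function(cts, control_group,
                             reference_gene = NULL) {
  stopifnot(is.data.frame(cts),
            all(c("sample", "group", "gene", "ct") %in% names(cts)))
  if (is.null(reference_gene))
    reference_gene <- attr(cts, "reference_gene") %||% "GAPDH"
  if (!control_group %in% cts$group)
    stop("control group '", control_group, "' not present")
  ref <- cts[cts$gene == reference_gene, c("sample", "ct")]
  if (nrow(ref) == 0L) stop("reference gene '", reference_gene, "' not present")
  targets <- cts[cts$gene != reference_gene, , drop = FALSE]
  miss <- setdiff(unique(targets$sample), ref$sample)
  if (length(miss))
    stop("reference gene missing for sample(s): ", paste(miss, collapse = ", "))
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  targets$dct <- targets$ct - ref_ct[targets$sample]
  agg <- stats::aggregate(dct ~ gene + group, data = targets, FUN = mean)
  out <- list()
  for (gene in unique(agg$gene)) {
    sub <- agg[agg$gene == gene, ]
    ctrl_dct <- sub$dct[sub$group == control_group]
    if (length(ctrl_dct) != 1L)
      stop("gene '", gene, "' has no control-group measurements")
    for (j in seq_len(nrow(sub))) {
      ddct <- sub$dct[j] - ctrl_dct
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, group = sub$group[j], delta_ct_mean = sub$dct[j],
        ddct = ddct, fold = 2^(-ddct), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
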