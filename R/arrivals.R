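#' Per-site-class normalized arrival fractions
#'
#' For each site class c, the normalized fraction is
#' (arrivals at class-c sites / number of molecules) / (number of
#' available class-c sites): the probability per molecule per available
#' site.  Classes with k = 1 or 3 adjacent dimers are reported (as
#' \code{excluded}) but are conventionally left out of the edge/lattice
#' comparison.
#'
#' @param table An \code{arrival_table}.
#' @param sites The \code{binding_site_list} (or its data.frame summary)
#'   the table was generated against.
#' @return data.frame with columns class, n_sites, arrivals, n_molecules,
#'   fraction.
#' @export
per_site_class_fractions <- function(table, sites) {
  sdf <- if (inherits(sites, "binding_site_list")) as.data.frame(sites)
         else sites
  n_mol <- nrow(table)
  classes <- sort(unique(c(sdf$classification,
                           stats::na.omit(table$site_class))))
  out <- do.call(rbind, lapply(classes, function(cl) {
    ns <- sum(sdf$classification == cl)
    if (ns == 0) stop(sprintf("class '%s' has zero available sites", cl))
    arr <- sum(table$status == "arrived" &
                 !is.na(table$site_class) & table$site_class == cl)
    data.frame(class = cl, n_sites = ns, arrivals = arr,
               n_molecules = n_mol, fraction = (arr / n_mol) / ns)
  }))
  rownames(out) <- NULL
  out
}

#' Edge / lattice per-site preference
#'
#' Ratio of the per-site normalized arrival fraction at k = 2 edge sites
#' to that at k = 4 lattice sites.
#'
#' @inheritParams per_site_class_fractions
#' @return List with the two fractions, the fold ratio, and the counts.
#' @export
edge_lattice_fold <- function(table, sites) {
  fr <- per_site_class_fractions(table, sites)
  e <- fr[fr$class == "edge", ]
  l <- fr[fr$class == "lattice", ]
  if (nrow(e) == 0 || nrow(l) == 0)
    stop("need both edge and lattice sites for the fold")
  list(edge_fraction = e$fraction, lattice_fraction = l$fraction,
       fold = e$fraction / l$fraction,
       edge_arrivals = e$arrivals, lattice_arrivals = l$arrivals,
       edge_sites = e$n_sites, lattice_sites = l$n_sites)
}

#' Compare total arrivals between two configurations
#'
#' Percent change in the mean number of arrival events per microtubule
#' (per replicate) between two equal-size ensembles, with an exact
#' binomial test on the pooled arrival counts and a nonparametric
#' bootstrap confidence interval over replicates.
#'
#' @param table_a,table_b Arrival tables with equal molecules per
#'   replicate; a is the test condition (e.g. tapered), b the reference
#'   (e.g. blunt).
#' @param n_boot Bootstrap resamples.
#' @return An object of class \code{"fold_comparison"}: percent change,
#'   per-replicate means, binomial p-value, bootstrap CI.
#' @export
compare_configurations <- function(table_a, table_b, n_boot = 2000) {
  per_rep <- function(tab) {
    tapply(tab$status == "arrived", tab$replicate, sum)
  }
  ra <- per_rep(table_a); rb <- per_rep(table_b)
  na <- nrow(table_a); nb <- nrow(table_b)
  if (length(unique(c(table(table_a$replicate),
                      table(table_b$replicate)))) != 1)
    stop("replicates must have equal molecule counts")
  ma <- mean(ra); mb <- mean(rb)
  pct <- 100 * (ma - mb) / mb
  # binomial test: pooled arrivals of A among all arrivals, against the
  # molecule-count proportion
  ka <- sum(ra); kb <- sum(rb)
  pv <- stats::binom.test(ka, ka + kb, p = na / (na + nb))$p.value
  boot <- replicate(n_boot, {
    100 * (mean(sample(ra, replace = TRUE)) /
             mean(sample(rb, replace = TRUE)) - 1)
  })
  structure(list(percent_change = pct, mean_a = ma, mean_b = mb,
                 p_value = pv,
                 ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
                 per_replicate_a = ra, per_replicate_b = rb),
            class = "fold_comparison")
}

#' @export
print.fold_comparison <- function(x, ...) {
  cat(sprintf(
    "<fold_comparison: %+.1f%% change (means %.1f vs %.1f); p = %.3g; 95%% CI [%.1f, %.1f]>\n",
    x$percent_change, x$mean_a, x$mean_b, x$p_value, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Electron-microscopy bead-count statistics
#'
#' Worked-example calculator for gold-bead counts classified by binding
#' location: (a) the raw fold of defect/sheet-bound over lattice-bound
#' beads, (b) the same fold normalized to the observed microtubule length
#' in each category, and (c) the per-site edge preference obtained by
#' multiplying the sheet-edge : sheet-middle bead ratio by the total :
#' edge site-density ratio per layer of an open sheet (2 edge sites out
#' of 14 per layer, so a 7-fold observed edge : middle bead ratio implies
#' a 7 x 14/2 = 49-fold per-site preference).
#'
#' @param counts Named list/vector with \code{lattice},
#'   \code{defect_or_sheet}, and optionally \code{sheet_edge},
#'   \code{sheet_middle}.
#' @param lengths Optional named list/vector (\code{lattice},
#'   \code{defect_or_sheet}) of observed microtubule lengths per
#'   category (same units).
#' @param site_ratio Total:edge binding-site ratio per sheet layer,
#'   default \code{c(total = 14, edge = 2)}.
#' @param middle_normalization Use middle:edge site densities (12:2)
#'   instead of total:edge (14:2) for the per-site preference.
#' @return List with \code{raw_fold}, \code{length_normalized_fold} (NA
#'   without lengths), \code{edge_middle_ratio}, and
#'   \code{per_site_edge_preference} (NA without sheet counts).
#' @export
em_bead_statistics <- function(counts, lengths = NULL,
                               site_ratio = c(total = 14, edge = 2),
                               middle_normalization = FALSE) {
  counts <- as.list(counts)
  if (counts$lattice <= 0) stop("lattice count must be positive")
  raw <- counts$defect_or_sheet / counts$lattice
  lnorm <- NA_real_
  if (!is.null(lengths)) {
    lengths <- as.list(lengths)
    if (lengths$lattice <= 0 || lengths$defect_or_sheet <= 0)
      stop("lengths must be positive")
    lnorm <- (counts$defect_or_sheet / lengths$defect_or_sheet) /
             (counts$lattice / lengths$lattice)
  }
  emr <- NA_real_; pref <- NA_real_
  if (!is.null(counts$sheet_edge) && !is.null(counts$sheet_middle)) {
    if (counts$sheet_middle <= 0) stop("sheet_middle count must be positive")
    emr <- counts$sheet_edge / counts$sheet_middle
    dens <- if (middle_normalization)
      (site_ratio[["total"]] - site_ratio[["edge"]]) / site_ratio[["edge"]]
    else site_ratio[["total"]] / site_ratio[["edge"]]
    pref <- emr * dens
  }
  list(raw_fold = raw, length_normalized_fold = lnorm,
       edge_middle_ratio = emr, per_site_edge_preference = unname(pref))
}

#' Export arrival positions over the lattice
#'
#' Writes a CSV of arrival-site coordinates (one row per arrived
#' molecule) and renders a 3D-projection scatter of the lattice dimer
#' centres with arrival events overlaid.
#'
#' @param table An \code{arrival_table}.
#' @param mt The \code{microtubule_model}.
#' @param sites The matching \code{binding_site_list}.
#' @param path Output stem; writes \code{<path>.csv} and
#'   \code{<path>.png}.
#' @return Invisibly the CSV path.
#' @export
export_arrival_map <- function(table, mt, sites, path) {
  arr <- table[table$status == "arrived", , drop = FALSE]
  ctrs <- t(vapply(sites, `[[`, numeric(3), "site_center"))
  coords <- if (nrow(arr) > 0)
    data.frame(replicate = arr$replicate, molecule = arr$molecule,
               site_id = arr$site_id, k = arr$k,
               x = ctrs[arr$site_id, 1], y = ctrs[arr$site_id, 2],
               z = ctrs[arr$site_id, 3])
  else data.frame(replicate = integer(0), molecule = integer(0),
                  site_id = integer(0), k = integer(0),
                  x = numeric(0), y = numeric(0), z = numeric(0))
  csv <- paste0(path, ".csv")
  utils::write.csv(coords, csv, row.names = FALSE)
  png <- paste0(path, ".png")
  grDevices::png(png, width = 700, height = 900)
  on.exit(grDevices::dev.off())
  # unroll: plot axial position vs azimuth
  az <- atan2(mt$centers[, 2], mt$centers[, 1])
  graphics::plot(az, mt$centers[, 3], pch = 15, cex = 1.6, col = "grey70",
                 xlab = "azimuth (rad)", ylab = "axial position (nm)",
                 main = sprintf("%s: %d arrivals / %d molecules",
                                mt$config, nrow(arr), nrow(table)))
  if (nrow(coords) > 0) {
    saz <- atan2(coords$y, coords$x)
    graphics::points(saz, coords$z, pch = 19, col = "red", cex = 1.0)
  }
  invisible(csv)
}
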