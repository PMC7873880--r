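# Synthetic SNP genotype panels with tunable, distance-dependent LD decay.
#
# The generator emulates two contrasting diversity panels: a "maize-like"
# panel whose pairwise r2 decays to ~0.10 within ~10 kb, and a "soybean-like"
# panel where the same decay takes ~1 Mb.  Individuals are mosaics of a small
# pool of founder haplotypes; founder haplotypes themselves carry internal LD
# through a distance-decaying AR(1) Gaussian latent process thresholded at
# per-site allele-frequency quantiles.  Two length scales fall out of this:
# the founder LD length (dominates short-range r2) and the template switch
# rate of the copying process (kills founder sharing, hence LD, at long
# range).  The preset constants below were fixed once by the decay-curve
# calibration experiment shipped in analysis/02_ld_calibration.R.

#' LD-decay profile for the synthetic genotype generator
#'
#' Bundles the constants that control distance-dependent linkage
#' disequilibrium in [generate_genotypes()].  Two calibrated presets are
#' provided: `"maize-like"` (rapid decay: mean r2 reaches ~0.10 near 10 kb,
#' clustered marker spacing as in genotyping-by-sequencing panels) and
#' `"soybean-like"` (slow decay: mean r2 reaches ~0.10 near 1 Mb, even
#' array-like spacing).
#'
#' @param name `"maize-like"`, `"soybean-like"`, or any other label for a
#'   custom profile (custom profiles must supply all constants).
#' @param n_founder_haplotypes Size of the founder haplotype pool (>= 2).
#' @param copy_switch_rate Per-base-pair rate of switching founder template
#'   while copying; between markers `d` bp apart a template switch occurs
#'   with probability `1 - exp(-copy_switch_rate * d)`.
#' @param founder_ld_length_bp Correlation length (bp) of the AR(1) latent
#'   process that gives founder haplotypes their internal LD.
#' @param marker_spacing_bp Mean inter-marker distance in bp.
#' @param cluster_fraction Fraction of inter-marker gaps drawn from the short
#'   "cluster" spacing component (0 for even spacing).
#' @param cluster_spacing_bp Mean of the short spacing component in bp.
#' @param target_decay_distance_bp Distance at which mean pairwise r2 is
#'   expected to reach ~0.10; used by calibration checks, not by generation.
#' @return An object of class `ld_profile`.
#' @examples
#' ld_profile("maize-like")
#' @export
ld_profile <- function(name = c("maize-like", "soybean-like"),
                       n_founder_haplotypes = NULL,
                       copy_switch_rate = NULL,
                       founder_ld_length_bp = NULL,
                       marker_spacing_bp = NULL,
                       cluster_fraction = NULL,
                       cluster_spacing_bp = NULL,
                       target_decay_distance_bp = NULL) {
  presets <- list(
    "maize-like" = list(
      n_founder_haplotypes = 512L,
      copy_switch_rate = 1 / 2e5,
      founder_ld_length_bp = 16000,
      marker_spacing_bp = 40000,
      cluster_fraction = 0.35,
      cluster_spacing_bp = 1000,
      target_decay_distance_bp = 1e4
    ),
    "soybean-like" = list(
      n_founder_haplotypes = 512L,
      copy_switch_rate = 1 / 2e7,
      founder_ld_length_bp = 1.6e6,
      marker_spacing_bp = 52000,
      cluster_fraction = 0,
      cluster_spacing_bp = 2000,
      target_decay_distance_bp = 1e6
    )
  )
  if (length(name) > 1L || name %in% names(presets)) {
    name <- match.arg(name)
    p <- presets[[name]]
  } else {
    p <- list()
  }
  p$name <- name
  override <- list(
    n_founder_haplotypes = n_founder_haplotypes,
    copy_switch_rate = copy_switch_rate,
    founder_ld_length_bp = founder_ld_length_bp,
    marker_spacing_bp = marker_spacing_bp,
    cluster_fraction = cluster_fraction,
    cluster_spacing_bp = cluster_spacing_bp,
    target_decay_distance_bp = target_decay_distance_bp
  )
  for (nm in names(override)) if (!is.null(override[[nm]])) p[[nm]] <- override[[nm]]
  required <- names(override)
  missing <- required[vapply(p[required], is.null, logical(1))]
  if (length(missing))
    stop_invalid("custom ld_profile is missing constants: %s",
                 paste(missing, collapse = ", "))
  p$n_founder_haplotypes <- check_count(p$n_founder_haplotypes, "n_founder_haplotypes", min = 2L)
  if (p$copy_switch_rate <= 0) stop_invalid("copy_switch_rate must be > 0")
  if (p$target_decay_distance_bp <= 0) stop_invalid("target_decay_distance_bp must be > 0")
  if (p$marker_spacing_bp <= 0) stop_invalid("marker_spacing_bp must be > 0")
  p$cluster_fraction <- check_fraction(p$cluster_fraction, "cluster_fraction")
  structure(p, class = "ld_profile")
}

#' @export
print.ld_profile <- function(x, ...) {
  cat(sprintf("LD profile '%s'\n", x$name))
  cat(sprintf("  founders: %d, founder LD length: %s bp, switch rate: 1/%s bp\n",
              x$n_founder_haplotypes, format(x$founder_ld_length_bp, big.mark = ","),
              format(round(1 / x$copy_switch_rate), big.mark = ",")))
  cat(sprintf("  mean spacing: %s bp (cluster fraction %.2f), r2 ~ 0.10 near %s bp\n",
              format(x$marker_spacing_bp, big.mark = ","), x$cluster_fraction,
              format(x$target_decay_distance_bp, big.mark = ",")))
  invisible(x)
}

new_genotype_panel <- function(dosages, map, ids) {
  storage.mode(dosages) <- "integer"
  rownames(dosages) <- ids
  colnames(dosages) <- map$id
  structure(list(dosages = dosages, map = map, ids = ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chr))))
  mafs <- marker_maf(x)
  cat(sprintf("  MAF: median %.3f [%.3f, %.3f]; missing entries: %d\n",
              stats::median(mafs, na.rm = TRUE), min(mafs, na.rm = TRUE),
              max(mafs, na.rm = TRUE), sum(is.na(x$dosages))))
  invisible(x)
}

validate_panel <- function(G) {
  if (!inherits(G, "genotype_panel")) stop_invalid("expected a `genotype_panel`")
  if (ncol(G$dosages) != nrow(G$map)) stop_invalid("marker map does not match dosage matrix")
  bad <- !is.na(G$dosages) & !(G$dosages %in% 0:2)
  if (any(bad)) stop_invalid("dosages outside {0,1,2} at %d entries", sum(bad))
  for (ch in unique(G$map$chr)) {
    p <- G$map$pos[G$map$chr == ch]
    if (any(diff(p) <= 0))
      stop_invalid("positions not strictly increasing on chromosome %s", ch)
  }
  invisible(G)
}

#' Minor allele frequency of every marker
#'
#' Frequency of the counted (generation-time minor) allele folded onto
#' `[0, 0.5]`.  Always computed on the current panel, so it reflects any
#' subsampling that has taken place.
#'
#' @param G A `genotype_panel` or a dosage matrix (individuals x markers).
#' @return Numeric vector of per-marker MAFs (NA for all-missing markers).
#' @export
marker_maf <- function(G) {
  X <- if (inherits(G, "genotype_panel")) G$dosages else G
  f <- colMeans(X, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

minor_allele_count <- function(X) {
  cnt <- colSums(X, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(X))
  pmin(cnt, tot - cnt)
}

#' Generate a synthetic SNP genotype panel
#'
#' Simulates biallelic dosages for mostly-inbred individuals over several
#' chromosomes, with distance-dependent LD controlled by an [ld_profile()].
#' Per chromosome, marker positions are laid down with (optionally clustered)
#' exponential gaps; a founder pool of haplotypes is drawn from a thresholded
#' AR(1) Gaussian process so founders carry internal LD; each gamete then
#' copies along the chromosome from a randomly chosen founder, switching
#' template between adjacent markers with probability
#' `1 - exp(-copy_switch_rate * gap)`.  An individual is two gametes, forced
#' identical (a selfed, fully homozygous line) with probability `inbreeding`.
#'
#' Dosages count the generation-time minor allele; realized frequencies drift
#' around the drawn spectrum (truncated uniform on `[0.025, 0.5]`), so some
#' markers may come out monomorphic and are expected to be removed by
#' [filter_markers()].
#'
#' @param n_individuals,n_chromosomes,markers_per_chromosome Panel dimensions.
#' @param profile An [ld_profile()] (or preset name).
#' @param inbreeding Probability that an individual is a selfed, fully
#'   homozygous line (default 1: inbred diversity panels).
#' @param seed Integer seed; output is a pure function of seed and arguments.
#' @return A `genotype_panel`: integer dosage matrix plus a marker map with
#'   chromosome, physical position (bp) and allele labels.
#' @examples
#' G <- generate_genotypes(50, 2, 100, ld_profile("maize-like"), seed = 1)
#' dim(G$dosages)
#' @export
generate_genotypes <- function(n_individuals, n_chromosomes, markers_per_chromosome,
                               profile = ld_profile("maize-like"),
                               inbreeding = 1, seed) {
  n <- check_count(n_individuals, "n_individuals")
  n_chr <- check_count(n_chromosomes, "n_chromosomes")
  m_chr <- check_count(markers_per_chromosome, "markers_per_chromosome")
  if (is.character(profile)) profile <- ld_profile(profile)
  if (!inherits(profile, "ld_profile")) stop_invalid("`profile` must be an ld_profile")
  inbreeding <- check_fraction(inbreeding, "inbreeding")
  if (missing(seed)) stop_invalid("`seed` is required")

  with_seed(seed, {
    n_gam <- 2L * n
    selfed <- stats::runif(n) < inbreeding
    blocks <- vector("list", n_chr)
    maps <- vector("list", n_chr)
    for (ch in seq_len(n_chr)) {
      gaps <- draw_gaps(m_chr, profile)
      pos <- cumsum(gaps)
      p <- maf_spectrum(gaps, profile$founder_ld_length_bp)
      H <- founder_haplotypes(profile$n_founder_haplotypes, gaps, p,
                              profile$founder_ld_length_bp)
      A <- copy_gametes(H, gaps, profile$copy_switch_rate, n_gam)
      g1 <- A[seq_len(n), , drop = FALSE]
      g2 <- A[n + seq_len(n), , drop = FALSE]
      g2[selfed, ] <- g1[selfed, ]
      blocks[[ch]] <- g1 + g2
      maps[[ch]] <- data.frame(
        id = sprintf("snp_%d_%d", ch, pos),
        chr = ch, pos = pos, a1 = "A", a2 = "C",
        stringsAsFactors = FALSE
      )
    }
    ids <- sprintf("ind_%04d", seq_len(n))
    G <- new_genotype_panel(do.call(cbind, blocks), do.call(rbind, maps), ids)
    validate_panel(G)
    G
  })
}

# Inter-marker gaps: mixture of a short "cluster" component and the main
# exponential component; first gap positions the first marker on the chromosome.
draw_gaps <- function(m, profile) {
  w <- profile$cluster_fraction
  long_mean <- if (w > 0 && w < 1) {
    (profile$marker_spacing_bp - w * profile$cluster_spacing_bp) / (1 - w)
  } else if (w == 0) profile$marker_spacing_bp else profile$cluster_spacing_bp
  short <- stats::runif(m) < w
  gaps <- numeric(m)
  gaps[short] <- stats::rexp(sum(short), 1 / profile$cluster_spacing_bp)
  gaps[!short] <- stats::rexp(sum(!short), 1 / long_mean)
  pmax(1, round(gaps))
}

# Allele-frequency spectrum: marginally truncated-uniform on [0.025, 0.5],
# but spatially autocorrelated (AR(1) latent on the same length scale as the
# founder LD) so that neighbouring sites have similar frequencies, as local
# drift and shared ascertainment produce in real panels.  Without this,
# frequency mismatch between tightly linked sites caps their attainable r2
# far below 1.
maf_spectrum <- function(gaps, ld_length) {
  m <- length(gaps)
  u <- numeric(m)
  u[1] <- stats::rnorm(1)
  if (m > 1) {
    rho <- exp(-gaps[-1] / ld_length)
    for (j in 2:m) u[j] <- rho[j - 1] * u[j - 1] + sqrt(1 - rho[j - 1]^2) * stats::rnorm(1)
  }
  0.025 + 0.475 * stats::pnorm(u)
}

# Founder pool: AR(1) latent Gaussian along the chromosome, thresholded so
# site j carries allele 1 ("A", the counted allele) with probability p[j].
founder_haplotypes <- function(n_f, gaps, p, ld_length) {
  m <- length(gaps)
  Z <- matrix(0, n_f, m)
  Z[, 1] <- stats::rnorm(n_f)
  if (m > 1) {
    rho <- exp(-gaps[-1] / ld_length)
    for (j in 2:m) {
      Z[, j] <- rho[j - 1] * Z[, j - 1] +
        sqrt(1 - rho[j - 1]^2) * stats::rnorm(n_f)
    }
  }
  thresholds <- stats::qnorm(p)
  H <- sweep(Z, 2, thresholds, `<=`)
  storage.mode(H) <- "integer"
  H
}

# Mosaic copying: each gamete follows one founder template, switching to a
# uniformly redrawn founder between adjacent markers at the profile's rate.
copy_gametes <- function(H, gaps, switch_rate, n_gam) {
  n_f <- nrow(H)
  m <- ncol(H)
  A <- matrix(0L, n_gam, m)
  cur <- sample.int(n_f, n_gam, replace = TRUE)
  A[, 1] <- H[cbind(cur, rep(1L, n_gam))]
  if (m > 1) {
    s <- 1 - exp(-switch_rate * gaps[-1])
    for (j in 2:m) {
      sw <- stats::runif(n_gam) < s[j - 1]
      if (any(sw)) cur[sw] <- sample.int(n_f, sum(sw), replace = TRUE)
      A[, j] <- H[cbind(cur, rep(j, n_gam))]
    }
  }
  A
}

#' Squared-correlation linkage disequilibrium between two dosage vectors
#'
#' Composite LD: the squared Pearson correlation of unphased allele dosages,
#' as computed by plink and simplePHENOTYPES on genotypes (haplotype-phase
#' r2 is never used in this package).
#'
#' @param x,y Equal-length dosage vectors (entries 0/1/2, NA allowed).
#' @return A single r2 value in `[0, 1]`.
#' @examples
#' pairwise_r2(c(0, 0, 2, 2), c(2, 2, 0, 0))  # 1: perfect negative correlation
#' @export
pairwise_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_invalid("`x` and `y` must have equal length >= 2")
  ok <- !is.na(x) & !is.na(y)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
    stop_invalid("LD undefined: monomorphic (constant) dosage vector")
  stats::cor(x[ok], y[ok])^2
}

# r2 of many column pairs of X at once (NA treated by complete pairs).
pairwise_r2_many <- function(X, ii, jj) {
  n <- nrow(X)
  out <- numeric(length(ii))
  chunk <- 5000L
  for (start in seq(1L, length(ii), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(ii))
    A <- X[, ii[idx], drop = FALSE]
    B <- X[, jj[idx], drop = FALSE]
    if (anyNA(A) || anyNA(B)) {
      out[idx] <- vapply(seq_along(idx), function(k) {
        a <- A[, k]; b <- B[, k]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 2 || stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) return(NA_real_)
        stats::cor(a[ok], b[ok])^2
      }, numeric(1))
    } else {
      ma <- colMeans(A); mb <- colMeans(B)
      va <- colMeans(A^2) - ma^2
      vb <- colMeans(B^2) - mb^2
      cab <- colMeans(A * B) - ma * mb
      r2 <- (cab^2) / (va * vb)
      r2[va == 0 | vb == 0] <- NA_real_
      out[idx] <- r2
    }
  }
  out
}

#' Filter a genotype panel: missingness, minor allele count, LD pruning
#'
#' Mirrors the marker quality control applied to the real diversity panels:
#' drop markers exceeding a missing-data fraction, drop markers below a minor
#' allele count, then LD-prune with plink's windowed greedy semantics
#' (`--indep-pairwise`-style): within each window of `prune_window` markers,
#' while any retained pair has r2 >= `prune_r2`, remove the member of the
#' worst pair with the smaller MAF (tie: the later marker); then advance the
#' window by `prune_step` markers.  Windows never span chromosomes and the
#' original marker order is preserved.
#'
#' @param G A `genotype_panel`.
#' @param max_missing Maximum tolerated missing fraction per marker.
#' @param min_mac Minimum minor allele count.
#' @param prune_r2 LD-pruning threshold on r2.
#' @param prune_window,prune_step Window size and step, in marker counts.
#' @return The filtered `genotype_panel`.
#' @export
filter_markers <- function(G, max_missing = 0.05, min_mac = 5,
                           prune_r2 = 0.9, prune_window = 100, prune_step = 10) {
  validate_panel(G)
  X <- G$dosages
  keep <- colMeans(is.na(X)) <= max_missing
  keep <- keep & minor_allele_count(X) >= min_mac
  mafs <- marker_maf(X)
  for (ch in unique(G$map$chr)) {
    on_chr <- which(G$map$chr == ch & keep)
    kept <- prune_chromosome(X, on_chr, mafs, prune_r2, prune_window, prune_step)
    keep[setdiff(on_chr, kept)] <- FALSE
  }
  if (!any(keep)) stop_invalid("all markers filtered out")
  new_genotype_panel(X[, keep, drop = FALSE], G$map[keep, , drop = FALSE], G$ids)
}

# Greedy windowed pruning over the (already quality-filtered) markers of one
# chromosome; `idx` are column indices into X, in map order.
prune_chromosome <- function(X, idx, mafs, prune_r2, prune_window, prune_step) {
  m <- length(idx)
  if (m < 2) return(idx)
  alive <- rep(TRUE, m)
  start <- 1L
  while (start <= m) {
    win <- start:min(start + prune_window - 1L, m)
    wi <- win[alive[win]]
    if (length(wi) >= 2) {
      repeat {
        cols <- idx[wi]
        R <- suppressWarnings(stats::cor(X[, cols, drop = FALSE],
                                         use = "pairwise.complete.obs"))^2
        R[is.na(R)] <- 0
        diag(R) <- 0
        worst <- max(R)
        if (worst < prune_r2) break
        pair <- which(R == worst, arr.ind = TRUE)[1, ]
        a <- wi[pair[1]]; b <- wi[pair[2]]
        drop_local <- if (mafs[idx[a]] < mafs[idx[b]]) a
                      else if (mafs[idx[b]] < mafs[idx[a]]) b
                      else max(a, b)
        alive[drop_local] <- FALSE
        wi <- setdiff(wi, drop_local)
        if (length(wi) < 2) break
      }
    }
    start <- start + prune_step
  }
  idx[alive]
}

#' Nested subsampling of individuals
#'
#' Draws a chain of nested subpanels (each panel's individuals a subset of
#' the previous panel's), emulating nested diversity-panel subsamples such as
#' a 2,815 / 1,000 / 500 accession series.  Markers are unchanged; MAFs and
#' minor allele counts should be recomputed on each subpanel.
#'
#' @param G A `genotype_panel`.
#' @param sizes Strictly decreasing vector of subsample sizes; the first may
#'   equal `n_individuals`.
#' @param seed Integer seed.
#' @return A list of `genotype_panel`s, one per size.
#' @export
nested_subsample <- function(G, sizes, seed) {
  validate_panel(G)
  if (length(sizes) < 1 || any(diff(sizes) >= 0))
    stop_invalid("`sizes` must be strictly decreasing")
  if (sizes[1] > nrow(G$dosages))
    stop_invalid("subsample size %d exceeds available individuals (%d)",
                 sizes[1], nrow(G$dosages))
  if (any(sizes < 1)) stop_invalid("subsample sizes must be positive")
  with_seed(seed, {
    out <- vector("list", length(sizes))
    current <- seq_len(nrow(G$dosages))
    for (k in seq_along(sizes)) {
      current <- sort(sample(current, sizes[k]))
      out[[k]] <- new_genotype_panel(G$dosages[current, , drop = FALSE],
                                     G$map, G$ids[current])
    }
    out
  })
}

#' Mean pairwise r2 as a function of physical distance
#'
#' Samples intrachromosomal marker pairs, bins them by distance, and returns
#' the mean r2 per bin.  Used to verify and calibrate the LD-decay presets
#' against their target decay distance (mean r2 ~ 0.10).
#'
#' @param G A `genotype_panel`.
#' @param distance_bins Increasing vector of bin edges in bp.
#' @param max_pairs Maximum number of marker pairs to sample.
#' @param seed Integer seed for pair sampling.
#' @return A data frame with one row per bin: edges, midpoint, mean r2
#'   (NA for empty bins) and pair count.
#' @export
ld_decay_curve <- function(G, distance_bins = NULL, max_pairs = 50000, seed = 1) {
  validate_panel(G)
  tab <- table(G$map$chr)
  if (any(tab < 2)) stop_invalid("need >= 2 markers per chromosome")
  if (is.null(distance_bins)) {
    target <- max(G$map$pos) / 4
    distance_bins <- seq(0, target, length.out = 21)
  }
  pairs <- do.call(rbind, lapply(unique(G$map$chr), function(ch) {
    w <- which(G$map$chr == ch)
    cb <- utils::combn(w, 2)
    cbind(cb[1, ], cb[2, ])
  }))
  dist <- abs(G$map$pos[pairs[, 2]] - G$map$pos[pairs[, 1]])
  in_range <- dist <= max(distance_bins) & dist >= min(distance_bins)
  pairs <- pairs[in_range, , drop = FALSE]
  dist <- dist[in_range]
  if (nrow(pairs) > max_pairs) {
    sel <- with_seed(seed, sample(nrow(pairs), max_pairs))
    pairs <- pairs[sel, , drop = FALSE]
    dist <- dist[sel]
  }
  r2 <- pairwise_r2_many(G$dosages, pairs[, 1], pairs[, 2])
  bin <- cut(dist, distance_bins, include.lowest = TRUE)
  ok <- !is.na(r2)
  mean_r2 <- tapply(r2[ok], bin[ok], mean)
  n_pairs <- tapply(rep(1, sum(ok)), bin[ok], sum)
  lev <- levels(bin)
  data.frame(
    bin_low = distance_bins[-length(distance_bins)],
    bin_high = distance_bins[-1],
    midpoint = (distance_bins[-1] + distance_bins[-length(distance_bins)]) / 2,
    mean_r2 = as.numeric(mean_r2[lev]),
    n_pairs = ifelse(is.na(n_pairs[lev]), 0, n_pairs[lev]),
    row.names = NULL
  )
}
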