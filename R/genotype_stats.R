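#' Construct a marker-by-accession genotype matrix
#'
#' Co-dominant calls are stored as two integer allele matrices (unordered
#' pair per cell); `NA` in `a1` marks a missing call.
#'
#' @param a1,a2 Integer matrices (markers x accessions) of allele codes
#'   (>= 1); `a2` defaults to `a1` (homozygous calls).
#' @param marker_ids,accession_ids Dimension names.
#' @param groups Optional accession group labels (factor/character).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2 = a1,
                            marker_ids = rownames(a1),
                            accession_ids = colnames(a1),
                            groups = NULL) {
  stopifnot(is.matrix(a1), is.matrix(a2), all(dim(a1) == dim(a2)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(nrow(a1)))
  if (is.null(accession_ids)) accession_ids <- paste0("acc", seq_len(ncol(a1)))
  if (!is.null(groups)) stopifnot(length(groups) == ncol(a1))
  a2[is.na(a1)] <- NA_integer_
  if (any(stats::na.omit(c(a1, a2)) < 1)) stop("allele codes must be >= 1")
  dimnames(a1) <- dimnames(a2) <- list(marker_ids, accession_ids)
  structure(list(a1 = a1, a2 = a2, marker_ids = marker_ids,
                 accession_ids = accession_ids, groups = groups),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d markers x %d accessions (%.1f%% missing)%s\n",
              length(x$marker_ids), length(x$accession_ids),
              100 * mean(is.na(x$a1)),
              if (is.null(x$groups)) "" else
                sprintf(", %d groups", length(unique(x$groups)))))
  invisible(x)
}

#' Read / write genotype CSV
#'
#' CSV layout: rows are markers, columns accessions, cells `"a/b"` (an
#' unordered allele pair), `"a"` (homozygous) or `"-"` (missing).
#'
#' @param path File path.
#' @return [read_genotypes()]: a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE,
                         colClasses = "character")
  m <- as.matrix(tab)
  parse_cell <- function(cell) {
    if (is.na(cell) || cell == "-" || cell == "") return(c(NA_integer_, NA_integer_))
    parts <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1L]])
    if (length(parts) == 1L) parts <- c(parts, parts)
    parts[1:2]
  }
  parsed <- apply(m, c(1, 2), function(cell) parse_cell(cell)[1L])
  parsed2 <- apply(m, c(1, 2), function(cell) parse_cell(cell)[2L])
  genotype_matrix(parsed, parsed2, rownames(m), colnames(m))
}

#' @rdname read_genotypes
#' @param gm A [genotype_matrix()].
#' @export
write_genotypes <- function(gm, path) {
  cells <- matrix("-", nrow(gm$a1), ncol(gm$a1))
  ok <- !is.na(gm$a1)
  cells[ok] <- paste0(gm$a1[ok], "/", gm$a2[ok])
  out <- data.frame(marker_id = gm$marker_ids, cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("marker_id", gm$accession_ids)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Botstein polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` over allele frequencies
#' `p` (the marker-informativeness measure standard in genotyping software).
#'
#' @param p Numeric vector of allele frequencies (renormalized internally).
#' @return PIC in `[0, 1)`.
#' @export
pic_botstein <- function(p) {
  p <- p[p > 0] / sum(p[p > 0])
  s2 <- sum(p^2)
  cross <- (s2^2 - sum(p^4)) / 2   # sum over i<j of p_i^2 p_j^2
  1 - s2 - 2 * cross
}

#' Per-marker allele statistics
#'
#' Allele counts, polymorphic flag, Botstein PIC and expected heterozygosity
#' from the non-missing calls of each marker, plus panel means over the
#' markers with data. Allele frequencies are renormalized over observed
#' calls (frequency renormalization for missing data).
#'
#' @param gm A [genotype_matrix()] with >= 2 accessions.
#' @return List: `per_marker` data frame (`marker_id`, `n_alleles`,
#'   `polymorphic`, `pic`, `he`) and `panel` (means; `pct_polymorphic`).
#' @export
allele_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$accession_ids) < 2L) stop("need >= 2 accessions")
  per <- lapply(seq_along(gm$marker_ids), function(i) {
    al <- c(gm$a1[i, ], gm$a2[i, ])
    al <- al[!is.na(al)]
    if (!length(al))
      return(data.frame(marker_id = gm$marker_ids[i], n_alleles = NA_integer_,
                        polymorphic = NA, pic = NA_real_, he = NA_real_,
                        stringsAsFactors = FALSE))
    p <- as.numeric(table(al)) / length(al)
    data.frame(marker_id = gm$marker_ids[i], n_alleles = length(p),
               polymorphic = length(p) >= 2L, pic = pic_botstein(p),
               he = 1 - sum(p^2), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ok <- !is.na(per$n_alleles)
  panel <- list(mean_alleles = mean(per$n_alleles[ok]),
                pct_polymorphic = 100 * mean(per$polymorphic[ok]),
                mean_pic = mean(per$pic[ok]),
                mean_he = mean(per$he[ok]),
                n_markers_scored = sum(ok))
  list(per_marker = per, panel = panel)
}

#' Nei-Li band-sharing distance matrix
#'
#' Each observed allele of each marker is treated as one gel band
#' (co-dominant heterozygotes contribute both bands). For accessions x and
#' y, similarity `S = 2 * n_shared / (n_x + n_y)` over the markers scored in
#' both (pairwise deletion of missing data), and distance `D = 1 - S`.
#'
#' @param gm A [genotype_matrix()].
#' @return Symmetric accession x accession matrix of distances in `[0, 1]`
#'   with zero diagonal. A pair with no jointly scored marker is an error.
#' @export
nei_li_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  nacc <- length(gm$accession_ids)
  bands <- lapply(seq_len(nacc), function(j)
    lapply(seq_along(gm$marker_ids), function(i) {
      al <- c(gm$a1[i, j], gm$a2[i, j])
      unique(al[!is.na(al)])
    }))
  D <- matrix(0, nacc, nacc, dimnames = list(gm$accession_ids, gm$accession_ids))
  for (x in seq_len(nacc - 1L)) {
    for (y in (x + 1L):nacc) {
      shared <- 0L; nx <- 0L; ny <- 0L; scored <- FALSE
      for (i in seq_along(gm$marker_ids)) {
        bx <- bands[[x]][[i]]; by <- bands[[y]][[i]]
        if (!length(bx) || !length(by)) next
        scored <- TRUE
        shared <- shared + length(intersect(bx, by))
        nx <- nx + length(bx); ny <- ny + length(by)
      }
      if (!scored)
        stop("no jointly scored bands for pair ",
             gm$accession_ids[x], " / ", gm$accession_ids[y])
      D[x, y] <- D[y, x] <- 1 - 2 * shared / (nx + ny)
    }
  }
  D
}

.gm_subset_markers <- function(gm, idx) {
  genotype_matrix(gm$a1[idx, , drop = FALSE], gm$a2[idx, , drop = FALSE],
                  gm$marker_ids[idx], gm$accession_ids, gm$groups)
}

#' Neighbor-joining tree with marker bootstrap
#'
#' Saitou-Nei neighbor joining on a distance matrix (via [ape::nj()]), with
#' bootstrap support computed by resampling markers (matrix rows) with
#' replacement, rebuilding the Nei-Li distances and the tree, and counting
#' bipartition recovery. Deterministic given `seed`.
#'
#' @param dm Distance matrix (as from [nei_li_distance()]); >= 3 accessions,
#'   all finite.
#' @param gm Optional [genotype_matrix()]; required for bootstrapping.
#' @param n_bootstrap Bootstrap replicates (0 = none; published practice is
#'   1000).
#' @param seed RNG seed for the resampling.
#' @return An [ape] `phylo` tree (unrooted); when bootstrapped, internal
#'   `node.label` holds percent support and the `"n_bootstrap"`/`"seed"`
#'   attributes record the resampling metadata.
#' @export
nj_tree <- function(dm, gm = NULL, n_bootstrap = 0L, seed = 42L) {
  if (!all(is.finite(dm))) stop("non-finite distances")
  if (nrow(dm) < 3L) stop("need >= 3 accessions")
  tree <- ape::nj(stats::as.dist(dm))
  if (n_bootstrap > 0L) {
    if (is.null(gm)) stop("genotype matrix required for bootstrapping")
    nm <- length(gm$marker_ids)
    set.seed(seed)
    boots <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(nm, nm, replace = TRUE)
      boots[[b]] <- ape::nj(stats::as.dist(nei_li_distance(.gm_subset_markers(gm, idx))))
    }
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    tree$node.label <- round(100 * counts / n_bootstrap, 1)
    attr(tree, "n_bootstrap") <- n_bootstrap
    attr(tree, "seed") <- seed
  }
  tree
}

#' Chi-square goodness-of-fit segregation test
#'
#' Pearson chi-square (no continuity correction) of observed genotype-class
#' counts against an expected segregation ratio (e.g. 1:1 in a mapping
#' population), `df = classes - 1`, upper-tail p-value.
#'
#' @param observed Integer vector of observed counts per genotype class.
#' @param ratio Expected ratio (positive; same length as `observed`).
#' @return List: `chi2`, `df`, `p`.
#' @export
segregation_chi2 <- function(observed, ratio = c(1, 1)) {
  stopifnot(length(observed) == length(ratio), all(ratio > 0), sum(observed) > 0)
  expected <- sum(observed) * ratio / sum(ratio)
  if (any(expected == 0)) stop("expected count of zero")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Comparative-Ct relative expression (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt_sample - dCt_calibrator`; fold change `2^-ddCt`. The
#' calibrator condition has fold change 1 by construction.
#'
#' @param ct_target_sample,ct_ref_sample Target/reference-gene Ct in the
#'   sample condition.
#' @param ct_target_calibrator,ct_ref_calibrator Ct in the calibrator
#'   condition.
#' @return Fold change(s), vectorized.
#' @export
relative_expression <- function(ct_target_sample, ct_ref_sample,
                                ct_target_calibrator, ct_ref_calibrator) {
  stopifnot(all(is.finite(c(ct_target_sample, ct_ref_sample,
                            ct_target_calibrator, ct_ref_calibrator))))
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
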