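#' Primer design constraints
#'
#' Container of the hard constraints and soft-penalty weights used by
#' [design_ism_primers()] and [design_expression_primers()].
#'
#' @param primer_len `c(min, opt, max)` primer length in bases.
#' @param tm_c `c(min, opt, max)` melting temperature window, degrees C.
#' @param gc_pct `c(min, max)` GC content window, percent.
#' @param max_homopolymer Longest tolerated single-base run.
#' @param genomic_product `c(min, max)` genomic amplicon size window, bases.
#'   The default 100-1000 brackets the typical intron-spanning product size
#'   observed for this marker class (a few hundred bases).
#' @param cdna_product `c(min, max)` spliced-cDNA amplicon window, bases
#'   (expression-assay mode only).
#' @param flank_window Exonic flank window size, bases.
#' @param salt_mM Monovalent cation concentration for the Tm model, mM.
#' @param primer_uM Primer concentration for the Tm model, micromolar.
#' @param max_self_complement Longest tolerated perfect inverted repeat within
#'   a primer; candidates containing one longer than this are rejected
#'   (hairpin/self-dimer proxy).
#' @param weights Named numeric penalty weights: `tm` (per degree C from the
#'   Tm optimum), `len` (per base from the length optimum), `gc` (per percent
#'   outside the GC window), `tm_diff` (per degree C of Tm difference between
#'   mates), `end_run` (per base of 3'-terminal homopolymer beyond 1).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(primer_len = c(18L, 20L, 27L),
                               tm_c = c(57, 60, 63),
                               gc_pct = c(40, 60),
                               max_homopolymer = 4L,
                               genomic_product = c(100L, 1000L),
                               cdna_product = c(60L, 100L),
                               flank_window = 100L,
                               salt_mM = 50,
                               primer_uM = 0.25,
                               max_self_complement = 7L,
                               weights = c(tm = 1, len = 0.25, gc = 0.5,
                                           tm_diff = 0.5, end_run = 0.5)) {
  stopifnot(length(primer_len) == 3L, primer_len[1] <= primer_len[2], primer_len[2] <= primer_len[3],
            length(tm_c) == 3L, tm_c[1] <= tm_c[2], tm_c[2] <= tm_c[3],
            length(gc_pct) == 2L, gc_pct[1] <= gc_pct[2],
            length(genomic_product) == 2L, genomic_product[1] <= genomic_product[2],
            length(cdna_product) == 2L, cdna_product[1] <= cdna_product[2],
            flank_window >= primer_len[1])
  structure(list(primer_len = as.integer(primer_len), tm_c = as.numeric(tm_c),
                 gc_pct = as.numeric(gc_pct), max_homopolymer = as.integer(max_homopolymer),
                 genomic_product = as.integer(genomic_product),
                 cdna_product = as.integer(cdna_product),
                 flank_window = as.integer(flank_window),
                 salt_mM = salt_mM, primer_uM = primer_uM,
                 max_self_complement = as.integer(max_self_complement),
                 weights = weights),
            class = "design_constraints")
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); dinucleotides read 5'->3' on one strand.
.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation per terminal base pair
.init_dH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.init_dS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Nearest-neighbor melting temperature
#'
#' SantaLucia (1998) unified nearest-neighbor thermodynamics with the
#' entropic salt correction `dS + 0.368 * (N-1) * ln([Na+])` and
#' `Tm = 1000 * dH / (dS_corrected + R * ln(C_T / 4)) - 273.15`
#' (R = 1.987 cal/(mol K), non-self-complementary duplex assumption). The
#' parameter table is fixed so results are reproducible by hand.
#'
#' @param seq Character vector of primer sequences (length >= 8, `A,C,G,T`
#'   only).
#' @param salt_mM Monovalent cation concentration, mM.
#' @param primer_uM Total strand concentration, micromolar.
#' @return Numeric vector of melting temperatures in degrees C.
#' @export
melting_temperature <- function(seq, salt_mM = 50, primer_uM = 0.25) {
  vapply(seq, function(s) {
    if (is.na(s) || nchar(s) < 8L) stop("primer sequence must be >= 8 bases")
    if (grepl("[^ACGT]", s)) stop("primer sequence must contain only A,C,G,T: ", s)
    n <- nchar(s)
    b <- strsplit(s, "")[[1L]]
    di <- paste0(b[-n], b[-1L])
    dH <- sum(.nn_dH[di]) + .init_dH[[b[1L]]] + .init_dH[[b[n]]]
    dS <- sum(.nn_dS[di]) + .init_dS[[b[1L]]] + .init_dS[[b[n]]]
    dS_salt <- dS + 0.368 * (n - 1) * log(salt_mM / 1000)
    1000 * dH / (dS_salt + 1.987 * log(primer_uM * 1e-6 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Wallace-rule melting temperature
#'
#' The `2(A+T) + 4(G+C)` short-oligo rule; a sanity-check formula, not the
#' production Tm model.
#'
#' @inheritParams melting_temperature
#' @return Numeric vector, degrees C.
#' @export
tm_wallace <- function(seq) {
  vapply(seq, function(s) {
    b <- strsplit(s, "")[[1L]]
    2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

.gc_pct <- function(seq) {
  vapply(seq, function(s) {
    b <- strsplit(s, "")[[1L]]
    100 * sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

.max_run <- function(s) {
  r <- rle(strsplit(s, "")[[1L]])
  max(r$lengths)
}

.end_run <- function(s) {
  r <- rle(strsplit(s, "")[[1L]])
  r$lengths[length(r$lengths)]
}

# longest k such that some k-mer of s has its reverse complement also in s
.has_self_complement <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(FALSE)
  kmers <- substring(s, 1:(n - k + 1L), k:n)
  any(.revcomp(kmers) %in% kmers)
}

#' Soft penalty of a single primer
#'
#' `w_tm * |Tm - Tm_opt| + w_len * |len - len_opt| + w_gc * (distance of GC
#' outside the window) + w_end_run * (3'-terminal homopolymer length - 1)`.
#' Lower is better; a perfect primer scores 0.
#'
#' @param tm Melting temperature, degrees C.
#' @param len Primer length, bases.
#' @param gc GC content, percent.
#' @param end_run Length of the homopolymer run ending at the 3' terminus.
#' @param constraints A [design_constraints()] object.
#' @return Numeric penalty (vectorized).
#' @export
primer_penalty <- function(tm, len, gc, end_run, constraints = design_constraints()) {
  w <- constraints$weights
  gc_out <- pmax(0, constraints$gc_pct[1] - gc) + pmax(0, gc - constraints$gc_pct[2])
  w[["tm"]] * abs(tm - constraints$tm_c[2]) +
    w[["len"]] * abs(len - constraints$primer_len[2]) +
    w[["gc"]] * gc_out +
    w[["end_run"]] * pmax(0, end_run - 1)
}

# Enumerate acceptable primer windows within one flank.
# side = "left": forward primers read directly off the flank; dist = distance
#   from the primer 5' end to the intron boundary (flank right edge).
# side = "right": reverse primers are reverse complements of flank windows;
#   dist = distance from the primer 5' end to the intron boundary (flank left
#   edge).
.enumerate_side <- function(flank, side, constraints) {
  fl <- nchar(flank)
  cn <- constraints
  out <- list()
  for (L in cn$primer_len[1]:cn$primer_len[3]) {
    if (L > fl) next
    starts <- 0:(fl - L)                      # 0-based offset within flank
    seqs <- substring(flank, starts + 1L, starts + L)
    keep <- !grepl("N", seqs, fixed = TRUE)
    if (!any(keep)) next
    starts <- starts[keep]; seqs <- seqs[keep]
    if (side == "right") seqs <- .revcomp(seqs)
    gc <- .gc_pct(seqs)
    keep <- gc >= cn$gc_pct[1] & gc <= cn$gc_pct[2]
    if (!any(keep)) next
    starts <- starts[keep]; seqs <- seqs[keep]; gc <- gc[keep]
    runs <- vapply(seqs, .max_run, numeric(1), USE.NAMES = FALSE)
    keep <- runs <= cn$max_homopolymer
    if (!any(keep)) next
    starts <- starts[keep]; seqs <- seqs[keep]; gc <- gc[keep]
    sc <- vapply(seqs, .has_self_complement, logical(1),
                 k = cn$max_self_complement + 1L, USE.NAMES = FALSE)
    keep <- !sc
    if (!any(keep)) next
    starts <- starts[keep]; seqs <- seqs[keep]; gc <- gc[keep]
    tm <- melting_temperature(seqs, cn$salt_mM, cn$primer_uM)
    keep <- tm >= cn$tm_c[1] & tm <= cn$tm_c[3]
    if (!any(keep)) next
    starts <- starts[keep]; seqs <- seqs[keep]; gc <- gc[keep]; tm <- tm[keep]
    dist <- if (side == "left") fl - starts else starts + L
    er <- vapply(seqs, .end_run, numeric(1), USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      seq = seqs, flank_offset = starts, len = L, dist = as.integer(dist),
      tm = tm, gc = gc, end_run = er,
      penalty = primer_penalty(tm, L, gc, er, cn),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$penalty, df$flank_offset, df$len), , drop = FALSE]
}

.empty_pairs <- function(reason = NULL) {
  df <- data.frame(fwd_seq = character(0), rev_seq = character(0),
                   fwd_pos = integer(0), rev_pos = integer(0),
                   fwd_dist = integer(0), rev_dist = integer(0),
                   fwd_tm = numeric(0), rev_tm = numeric(0),
                   fwd_gc = numeric(0), rev_gc = numeric(0),
                   genomic_amplicon_len = integer(0), cdna_amplicon_len = integer(0),
                   penalty = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(reason)) attr(df, "reason") <- reason
  df
}

# chromosome coordinate (0-based) of a primer 5' base given the intron row
.primer_positions <- function(intron, fwd_dist, rev_dist) {
  if (intron$strand == "+") {
    list(fwd = intron$start - fwd_dist, rev = intron$end + rev_dist - 1L)
  } else {
    list(fwd = intron$end + fwd_dist - 1L, rev = intron$start - rev_dist)
  }
}

#' Design intron-spanning primer pairs
#'
#' Enumerates forward-primer windows in the left (5') exonic flank and
#' reverse-primer windows in the right (3') flank of an intron, applies all
#' hard constraints (length, Tm, GC, homopolymer, self-complementarity,
#' genomic product size) and returns surviving pairs ranked by ascending
#' penalty. The genomic amplicon runs from the forward primer 5' end to the
#' reverse primer 5' end and always spans the target intron:
#' `genomic_amplicon_len = fwd_dist + intron_len + rev_dist`, where the dist
#' terms are the distances of the primer 5' ends from the intron boundaries.
#'
#' Flanks shorter than the minimum primer length, or containing `N`, yield an
#' empty result whose `"reason"` attribute names the cause.
#'
#' @param intron One intron row as returned by [extract_introns()] (data
#'   frame row or list with `sequence`, `left_flank`, `right_flank`,
#'   `start`, `end`, `strand`, `intron_len`).
#' @param constraints A [design_constraints()] object.
#' @param max_per_side Candidate primers retained per flank (by penalty)
#'   before pairing; bounds the search deterministically.
#' @return Data frame of primer pairs sorted by `penalty`: sequences (5'->3'),
#'   chromosome coordinates of the 5' ends (`fwd_pos`, `rev_pos`, 0-based),
#'   distances to the intron boundaries, per-primer Tm and GC, genomic and
#'   cDNA amplicon lengths and the pair penalty.
#' @export
design_ism_primers <- function(intron, constraints = design_constraints(),
                               max_per_side = 12L) {
  if (is.data.frame(intron)) intron <- as.list(intron[1L, ])
  cn <- constraints
  if (nchar(intron$left_flank) < cn$primer_len[1] || nchar(intron$right_flank) < cn$primer_len[1])
    return(.empty_pairs("flank_too_short"))
  if (grepl("N", intron$left_flank, fixed = TRUE) || grepl("N", intron$right_flank, fixed = TRUE))
    return(.empty_pairs("flank_has_n"))
  lf <- .enumerate_side(intron$left_flank, "left", cn)
  rf <- .enumerate_side(intron$right_flank, "right", cn)
  if (is.null(lf) || is.null(rf)) return(.empty_pairs("no_candidate_primer"))
  lf <- utils::head(lf, max_per_side)
  rf <- utils::head(rf, max_per_side)
  grid <- expand.grid(f = seq_len(nrow(lf)), r = seq_len(nrow(rf)))
  f <- lf[grid$f, ]; r <- rf[grid$r, ]
  amp <- f$dist + intron$intron_len + r$dist
  keep <- amp >= cn$genomic_product[1] & amp <= cn$genomic_product[2]
  if (!any(keep)) return(.empty_pairs("no_pair_in_product_window"))
  f <- f[keep, ]; r <- r[keep, ]; amp <- amp[keep]
  pen <- f$penalty + r$penalty + cn$weights[["tm_diff"]] * abs(f$tm - r$tm)
  pos <- .primer_positions(intron, f$dist, r$dist)
  out <- data.frame(fwd_seq = f$seq, rev_seq = r$seq,
                    fwd_pos = pos$fwd, rev_pos = pos$rev,
                    fwd_dist = f$dist, rev_dist = r$dist,
                    fwd_tm = f$tm, rev_tm = r$tm,
                    fwd_gc = f$gc, rev_gc = r$gc,
                    genomic_amplicon_len = as.integer(amp),
                    cdna_amplicon_len = as.integer(f$dist + r$dist),
                    penalty = pen, stringsAsFactors = FALSE)
  out <- out[order(out$penalty, out$fwd_dist, out$rev_dist, out$fwd_seq, out$rev_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design expression-assay primer pairs
#'
#' Like [design_ism_primers()] but additionally requires the spliced-cDNA
#' amplicon (`fwd_dist + rev_dist`, the exonic part of the genomic product)
#' to fall within the `cdna_product` window, so that a compact product is
#' amplified from cDNA while the genomic product still spans the intron and
#' the two templates remain distinguishable.
#'
#' @inheritParams design_ism_primers
#' @param gene Optional [gene_model] the intron belongs to (interface
#'   completeness; not needed for the computation).
#' @return As [design_ism_primers()].
#' @export
design_expression_primers <- function(intron, gene = NULL,
                                      constraints = design_constraints(),
                                      max_per_side = 12L) {
  pairs <- design_ism_primers(intron, constraints, max_per_side)
  if (!nrow(pairs)) return(pairs)
  keep <- pairs$cdna_amplicon_len >= constraints$cdna_product[1] &
    pairs$cdna_amplicon_len <= constraints$cdna_product[2]
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) attr(out, "reason") <- "no_pair_in_cdna_window"
  out
}

#' Select up to k markers per gene
#'
#' Ranks each gene's candidate primer pairs preferring distinct target
#' introns first (the best pair of each intron, ordered by penalty), then
#' additional pairs by ascending penalty, and keeps at most `k` per gene.
#'
#' @param candidates Data frame of candidate pairs with at least `gene_id`,
#'   `intron_ordinal` and `penalty` columns.
#' @param k Maximum markers per gene (`Inf` keeps all, `0` none).
#' @return The selected rows, ordered by gene then rank.
#' @export
select_markers_per_gene <- function(candidates, k = 4L) {
  if (!nrow(candidates) || k == 0) return(candidates[0L, , drop = FALSE])
  pieces <- lapply(split(candidates, candidates$gene_id), function(g) {
    g <- g[order(g$penalty, g$intron_ordinal), , drop = FALSE]
    # within-intron rank: 1 for the best pair of each intron, 2 for second...
    r <- stats::ave(seq_len(nrow(g)), g$intron_ordinal, FUN = seq_along)
    g <- g[order(r, g$penalty, g$intron_ordinal), , drop = FALSE]
    utils::head(g, if (is.finite(k)) k else nrow(g))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Assign marker identifiers in chromosome-then-position order
#'
#' @param markers Marker data frame with `seq_id` and amplicon start
#'   coordinates (`fwd_pos`/`rev_pos`).
#' @param prefix Identifier prefix (e.g. `"OsISM"`).
#' @return `markers` with a `marker_id` column, re-ordered chromosome-then-
#'   position.
#' @export
assign_marker_ids <- function(markers, prefix = "OsISM") {
  if (!nrow(markers)) {
    markers$marker_id <- character(0)
    return(markers)
  }
  pos <- pmin(markers$fwd_pos, markers$rev_pos)
  tie <- if (!is.null(markers$fwd_seq)) markers$fwd_seq else
    if (!is.null(markers$parent_ism_id)) markers$parent_ism_id else seq_len(nrow(markers))
  ord <- order(markers$seq_id, pos, tie)
  markers <- markers[ord, , drop = FALSE]
  markers$marker_id <- sprintf("%s%05d", prefix, seq_len(nrow(markers)))
  rownames(markers) <- NULL
  markers[, c("marker_id", setdiff(names(markers), "marker_id")), drop = FALSE]
}

#' Design ISM markers across a whole annotated genome
#'
#' Runs [design_ism_primers()] (or [design_expression_primers()] in
#' expression mode) on every intron of every gene model, keeps the best
#' candidates per intron, applies the per-gene cap via
#' [select_markers_per_gene()], optionally verifies genome-wide primer
#' uniqueness by in-silico PCR, and assigns `OsISM#####` identifiers in
#' chromosome-then-position order. Deterministic: no randomness is used.
#'
#' @param genome Named character vector (reference genome).
#' @param models Named list of [gene_model] objects.
#' @param constraints A [design_constraints()] object.
#' @param per_gene Maximum markers per gene (`Inf` = one per designable
#'   intron).
#' @param mode `"genomic"` or `"expression"`.
#' @param check_uniqueness Verify with [primer_uniqueness()] that each pair
#'   amplifies exactly one genomic locus; non-unique markers are dropped.
#' @param max_product Product-size cap used for the uniqueness screen, bases.
#' @return Data frame of markers: `marker_id`, `gene_id`, `intron_ordinal`,
#'   `seq_id`, intron coordinates and length, primer columns from
#'   [design_ism_primers()]. Dropped non-unique pairs are recorded in the
#'   `"dropped"` attribute.
#' @export
design_genome_ism <- function(genome, models, constraints = design_constraints(),
                              per_gene = 4L, mode = c("genomic", "expression"),
                              check_uniqueness = TRUE, max_product = 3000L) {
  mode <- match.arg(mode)
  introns <- extract_all_introns(models, genome, flank = constraints$flank_window)
  cand <- list()
  if (!is.null(introns) && nrow(introns)) {
    for (i in seq_len(nrow(introns))) {
      row <- as.list(introns[i, ])
      pairs <- if (mode == "genomic") design_ism_primers(row, constraints)
               else design_expression_primers(row, constraints = constraints)
      if (!nrow(pairs)) next
      # per-gene selection may need fallback pairs on the same intron when the
      # cap exceeds the intron count; with an uncapped design one per intron
      pairs <- utils::head(pairs, if (is.finite(per_gene)) 3L else 1L)
      pairs <- cbind(data.frame(gene_id = row$gene_id, intron_ordinal = row$ordinal,
                                seq_id = row$seq_id, intron_start = row$start,
                                intron_end = row$end, strand = row$strand,
                                target_intron_len = row$intron_len,
                                stringsAsFactors = FALSE),
                     pairs)
      cand[[length(cand) + 1L]] <- pairs
    }
  }
  if (!length(cand)) {
    out <- cbind(data.frame(gene_id = character(0), intron_ordinal = integer(0),
                            seq_id = character(0), intron_start = integer(0),
                            intron_end = integer(0), strand = character(0),
                            target_intron_len = integer(0), stringsAsFactors = FALSE),
                 .empty_pairs())
    out$marker_id <- character(0)
    return(out)
  }
  cand <- do.call(rbind, cand)
  sel <- select_markers_per_gene(cand, per_gene)
  dropped <- NULL
  if (check_uniqueness && nrow(sel)) {
    uni <- vapply(seq_len(nrow(sel)), function(i)
      primer_uniqueness(sel$fwd_seq[i], sel$rev_seq[i], genome, max_product), character(1))
    dropped <- sel[uni != "unique", , drop = FALSE]
    if (nrow(dropped)) dropped$uniqueness <- uni[uni != "unique"]
    sel <- sel[uni == "unique", , drop = FALSE]
  }
  out <- assign_marker_ids(sel, prefix = "OsISM")
  attr(out, "dropped") <- dropped
  out
}

#' Write a marker table as TSV (1-based inclusive coordinates)
#'
#' @param markers Data frame from [design_genome_ism()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(markers, path) {
  out <- data.frame(marker_id = markers$marker_id,
                    gene_id = markers$gene_id,
                    intron_ordinal = markers$intron_ordinal,
                    seq_id = markers$seq_id,
                    fwd_seq = markers$fwd_seq,
                    rev_seq = markers$rev_seq,
                    fwd_start_1based = markers$fwd_pos + 1L,
                    rev_start_1based = markers$rev_pos + 1L,
                    fwd_tm = sprintf("%.2f", markers$fwd_tm),
                    rev_tm = sprintf("%.2f", markers$rev_tm),
                    genomic_amplicon_len = markers$genomic_amplicon_len,
                    cdna_amplicon_len = markers$cdna_amplicon_len,
                    penalty = sprintf("%.4f", markers$penalty),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
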