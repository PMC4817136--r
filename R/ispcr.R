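#' Find primer binding sites in a sequence
#'
#' Scans both strands of a template for near-exact primer matches (Hamming
#' distance, no indels). A site is reported when the primer binds with at
#' most `max_mismatch` mismatches and, when `require_3prime_exact` is set,
#' its 3'-terminal 3 bases match exactly (polymerase extension requirement).
#'
#' @param primer Primer sequence, 5'->3', length >= 15.
#' @param sequence Template DNA string.
#' @param max_mismatch Maximum tolerated mismatches.
#' @param require_3prime_exact Require an exact 3'-terminal trinucleotide.
#' @return Data frame with one row per site: `pos` (0-based template position
#'   of the primer 5' end; for minus-strand sites this is the template base
#'   that pairs with the primer 5' end), `strand` (`"+"`: primer matches the
#'   template as given, `"-"`: primer matches the reverse complement) and
#'   `mismatches`.
#' @export
find_binding_sites <- function(primer, sequence, max_mismatch = 2L,
                               require_3prime_exact = TRUE) {
  if (nchar(primer) < 15L) stop("primer must be >= 15 bases")
  n <- nchar(primer)
  subj <- Biostrings::DNAString(sequence)
  out <- list()

  scan <- function(pattern) {
    hits <- Biostrings::matchPattern(pattern, subj, max.mismatch = max_mismatch,
                                     with.indels = FALSE)
    if (!length(hits)) return(NULL)
    data.frame(start = Biostrings::start(hits), end = Biostrings::end(hits),
               seq = as.character(hits), stringsAsFactors = FALSE)
  }

  mm_count <- function(a, b) {
    mapply(function(x, y) sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]]), a, b,
           USE.NAMES = FALSE)
  }

  fwd <- scan(primer)
  if (!is.null(fwd)) {
    mm <- mm_count(fwd$seq, primer)
    keep <- rep(TRUE, nrow(fwd))
    if (require_3prime_exact)
      keep <- substr(fwd$seq, n - 2L, n) == substr(primer, n - 2L, n)
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(pos = fwd$start[keep] - 1L, strand = "+",
                                            mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  rc <- .revcomp(primer)
  rev <- scan(rc)
  if (!is.null(rev)) {
    mm <- mm_count(rev$seq, rc)
    keep <- rep(TRUE, nrow(rev))
    if (require_3prime_exact)
      keep <- substr(rev$seq, 1L, 3L) == substr(rc, 1L, 3L)
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(pos = rev$end[keep] - 1L, strand = "-",
                                            mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(pos = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict PCR amplicons for a primer pair
#'
#' Locates binding sites of both primers on every template sequence and
#' reports each convergent (inward-facing) site combination whose product is
#' no longer than `max_product` and at least as long as the two primers
#' combined. The product interval runs from the 5' end of the plus-strand
#' primer through the template base pairing with the 5' end of the
#' minus-strand primer.
#'
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param sequences Named character vector of templates (a genome, or spliced
#'   cDNAs).
#' @param max_product Maximum product size, bases.
#' @param max_mismatch,require_3prime_exact Passed to [find_binding_sites()].
#' @return Data frame: `seq_id`, `start`, `end` (0-based half-open product
#'   interval), `length`, `fwd_mismatches`, `rev_mismatches`, sorted by
#'   length.
#' @export
predict_amplicons <- function(fwd, rev, sequences, max_product = 3000L,
                              max_mismatch = 2L, require_3prime_exact = TRUE) {
  out <- list()
  min_len <- nchar(fwd) + nchar(rev)
  for (sid in names(sequences)) {
    fsites <- find_binding_sites(fwd, sequences[[sid]], max_mismatch, require_3prime_exact)
    rsites <- find_binding_sites(rev, sequences[[sid]], max_mismatch, require_3prime_exact)
    if (!nrow(fsites) || !nrow(rsites)) next
    # convergent combinations: one primer on + strand upstream, mate on - strand
    cross <- function(plus, minus, plus_is_fwd) {
      if (!nrow(plus) || !nrow(minus)) return(NULL)
      g <- expand.grid(p = seq_len(nrow(plus)), m = seq_len(nrow(minus)))
      data.frame(plus_pos = plus$pos[g$p], minus_pos = minus$pos[g$m],
                 fwd_mm = if (plus_is_fwd) plus$mismatches[g$p] else minus$mismatches[g$m],
                 rev_mm = if (plus_is_fwd) minus$mismatches[g$m] else plus$mismatches[g$p])
    }
    combos <- rbind(
      cross(fsites[fsites$strand == "+", ], rsites[rsites$strand == "-", ], TRUE),
      cross(rsites[rsites$strand == "+", ], fsites[fsites$strand == "-", ], FALSE))
    if (is.null(combos) || !nrow(combos)) next
    len <- combos$minus_pos - combos$plus_pos + 1L
    # product must contain both primer footprints
    keep <- len >= min_len & len <= max_product
    if (!any(keep)) next
    combos <- combos[keep, , drop = FALSE]; len <- len[keep]
    out[[length(out) + 1L]] <- data.frame(
      seq_id = sid, start = combos$plus_pos, end = combos$minus_pos + 1L,
      length = len, fwd_mismatches = combos$fwd_mm,
      rev_mismatches = combos$rev_mm, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      length = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$length, res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genome-wide primer-pair uniqueness
#'
#' A pair is `"unique"` when it predicts exactly one amplicon across the
#' whole genome, `"none"` when it predicts no amplicon, `"multi"` otherwise.
#' Uniqueness is assessed at the amplicon level, not the site level: isolated
#' binding sites that cannot pair into a product do not count against
#' specificity.
#'
#' @inheritParams predict_amplicons
#' @param genome Named character vector of chromosome sequences.
#' @return `"unique"`, `"multi"` or `"none"`.
#' @export
primer_uniqueness <- function(fwd, rev, genome, max_product = 3000L) {
  amps <- predict_amplicons(fwd, rev, genome, max_product)
  if (nrow(amps) == 0L) "none" else if (nrow(amps) == 1L) "unique" else "multi"
}

#' Splice a gene model into its cDNA sequence
#'
#' Exon sequences concatenated in transcription order, reported on the coding
#' strand.
#'
#' @param gene A [gene_model].
#' @param genome Named character vector containing the gene's chromosome.
#' @return Character scalar, the spliced cDNA.
#' @export
splice_cdna <- function(gene, genome) {
  stopifnot(inherits(gene, "gene_model"))
  chrom <- genome[[gene$seq_id]]
  ex <- gene$exons
  pieces <- substring(chrom, ex[, 1L] + 1L, ex[, 2L])
  cdna <- paste(pieces, collapse = "")
  if (gene$strand == "-") cdna <- .revcomp(cdna)
  cdna
}
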