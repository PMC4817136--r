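#' Karlin-Altschul bit score and E-value
#'
#' `bit = (lambda * raw - ln K) / ln 2` and `E = m * n * 2^-bit`, with the
#' effective search space taken as query length times total subject length
#' (no edge correction). The default `lambda = 1.28`, `K = 0.46` are the
#' ungapped parameters matching the +1/-2 nucleotide scoring used by the
#' homology search.
#'
#' @param raw Raw alignment score(s).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Bit score(s).
#' @export
karlin_bit_score <- function(raw, lambda = 1.28, K = 0.46) {
  (lambda * raw - log(K)) / log(2)
}

#' @rdname karlin_bit_score
#' @param bit Bit score(s).
#' @param m Query length, bases.
#' @param n Total subject length, bases.
#' @return E-value(s).
#' @export
karlin_evalue <- function(bit, m, n) {
  as.numeric(m) * as.numeric(n) * 2^(-bit)
}

#' Global affine-gap alignment
#'
#' Needleman-Wunsch alignment with Gotoh affine gaps. A gap of length L
#' scores `-(gap_open + gap_extend * L)`.
#'
#' @param a,b DNA strings (reference, query).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return List: `score`, `a_aln`, `b_aln` (gapped strings), `matches`,
#'   `aln_len`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -2, gap_open = 5, gap_extend = 2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  align_pair_cpp(a, b, match, mismatch, gap_open, gap_extend, 0L)
}

#' Local affine-gap alignment
#'
#' Smith-Waterman alignment with Gotoh affine gaps; same gap convention as
#' [align_global()].
#'
#' @inheritParams align_global
#' @return List: `score`, `a_aln`, `b_aln`, `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based half-open aligned spans), `matches`, `aln_len`.
#' @export
align_local <- function(a, b, match = 1, mismatch = -2, gap_open = 5, gap_extend = 2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  align_pair_cpp(a, b, match, mismatch, gap_open, gap_extend, 1L)
}

#' Semiglobal affine-gap alignment
#'
#' Aligns all of `a` against a local region of `b` (free leading/trailing
#' unaligned `b`); the form used to extract the full-length homolog of an
#' intron from a candidate query window, so that near-terminal InDels are
#' kept inside the aligned span rather than trimmed.
#'
#' @inheritParams align_global
#' @return As [align_local()]; `a_start`/`a_end` always span all of `a`.
#' @export
align_glocal <- function(a, b, match = 1, mismatch = -2, gap_open = 5, gap_extend = 2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  align_pair_cpp(a, b, match, mismatch, gap_open, gap_extend, 2L)
}

# extract raw gap runs from a pair of gapped strings
.gap_runs <- function(a_aln, b_aln) {
  av <- strsplit(a_aln, "")[[1L]]
  bv <- strsplit(b_aln, "")[[1L]]
  state <- ifelse(av == "-", "ins", ifelse(bv == "-", "del", "m"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ref_pos <- cumsum(c(0L, (av != "-")[-length(av)]))  # ref offset before each column
  runs <- which(r$values != "m")
  if (!length(runs))
    return(data.frame(ref_pos = integer(0), kind = character(0), length = integer(0),
                      allele_ref = character(0), allele_query = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(runs, function(i) {
    cols <- starts[i]:ends[i]
    kind <- if (r$values[i] == "ins") "insertion" else "deletion"
    data.frame(ref_pos = ref_pos[starts[i]],
               kind = kind, length = length(cols),
               allele_ref = if (kind == "deletion") paste(av[cols], collapse = "") else "",
               allele_query = if (kind == "insertion") paste(bv[cols], collapse = "") else "",
               stringsAsFactors = FALSE)
  }))
}

# left-normalize indel calls against the reference/query context
# (variant-normalization convention: shift a gap left while the flanking base
# matches the last base of the gapped allele, never crossing a previous call)
.normalize_indels <- function(calls, ref) {
  if (!nrow(calls)) return(calls)
  calls <- calls[order(calls$ref_pos), , drop = FALSE]
  floor_pos <- 0L
  for (i in seq_len(nrow(calls))) {
    p <- calls$ref_pos[i]
    L <- calls$length[i]
    if (calls$kind[i] == "deletion") {
      al <- calls$allele_ref[i]
      while (p > floor_pos && substr(ref, p, p) == substr(al, L, L)) {
        al <- paste0(substr(ref, p, p), substr(al, 1L, L - 1L))
        p <- p - 1L
      }
      calls$allele_ref[i] <- al
      floor_pos <- p + L
    } else {
      al <- calls$allele_query[i]
      while (p > floor_pos && substr(ref, p, p) == substr(al, L, L)) {
        al <- paste0(substr(ref, p, p), substr(al, 1L, L - 1L))
        p <- p - 1L
      }
      calls$allele_query[i] <- al
      floor_pos <- p
    }
    calls$ref_pos[i] <- p
  }
  # merge calls of the same kind that became adjacent after normalization
  out <- calls[0L, ]
  for (i in seq_len(nrow(calls))) {
    if (nrow(out)) {
      j <- nrow(out)
      touch_del <- out$kind[j] == "deletion" && calls$kind[i] == "deletion" &&
        out$ref_pos[j] + out$length[j] == calls$ref_pos[i]
      touch_ins <- out$kind[j] == "insertion" && calls$kind[i] == "insertion" &&
        out$ref_pos[j] == calls$ref_pos[i]
      if (touch_del || touch_ins) {
        out$length[j] <- out$length[j] + calls$length[i]
        out$allele_ref[j] <- paste0(out$allele_ref[j], calls$allele_ref[i])
        out$allele_query[j] <- paste0(out$allele_query[j], calls$allele_query[i])
        next
      }
    }
    out <- rbind(out, calls[i, ])
  }
  rownames(out) <- NULL
  out
}

#' Align two homologous sequences and call InDels
#'
#' Globally aligns a reference intron against its query-genome homolog with
#' affine gap penalties, merges each maximal gap run into a single call, and
#' left-normalizes the calls (each gap shifted to the smallest reference
#' position that preserves the alignment score, mirroring variant-
#' normalization practice) so positions are reproducible.
#'
#' @param ref_seq,query_seq Non-empty DNA strings (coding orientation).
#' @inheritParams align_global
#' @return List with `alignment` (from [align_global()]) and `indels`, a data
#'   frame of calls: `ref_pos` (0-based offset within `ref_seq`), `kind`
#'   (`"insertion"`/`"deletion"` relative to the reference), `length`,
#'   `allele_ref`, `allele_query`.
#' @export
align_and_call_indels <- function(ref_seq, query_seq, match = 1, mismatch = -2,
                                  gap_open = 5, gap_extend = 2) {
  aln <- align_global(ref_seq, query_seq, match, mismatch, gap_open, gap_extend)
  calls <- .gap_runs(aln$a_aln, aln$b_aln)
  calls <- .normalize_indels(calls, ref_seq)
  list(alignment = aln, indels = calls)
}

#' Apply InDel calls to a reference sequence
#'
#' Reconstructs the query sequence implied by a set of calls; the round-trip
#' identity `apply_indels(ref, calls) == query` (up to substitutions) is the
#' bookkeeping check used throughout the tests. Substitution differences are
#' not encoded by the calls, so the reconstruction uses the query alleles for
#' indel regions and reference residues elsewhere.
#'
#' @param ref Reference DNA string.
#' @param calls Data frame from [align_and_call_indels()].
#' @return Character scalar.
#' @export
apply_indels <- function(ref, calls) {
  if (!nrow(calls)) return(ref)
  calls <- calls[order(calls$ref_pos), , drop = FALSE]
  out <- character(0)
  cur <- 0L
  for (i in seq_len(nrow(calls))) {
    p <- calls$ref_pos[i]
    out <- c(out, substr(ref, cur + 1L, p))
    if (calls$kind[i] == "insertion") {
      out <- c(out, calls$allele_query[i])
      cur <- p
    } else {
      cur <- p + calls$length[i]
    }
  }
  paste0(paste(out, collapse = ""), substr(ref, cur + 1L, nchar(ref)))
}

#' Build a k-mer index of a query genome
#'
#' Exact-match seed lookup over the forward strand of every sequence; reverse-
#' strand hits are found by querying the reverse complement of the probe.
#' K-mers containing `N` are not indexed.
#'
#' @param query_genome Named character vector.
#' @param k K-mer size, 8..32.
#' @return An object of class `kmer_index`.
#' @export
build_query_index <- function(query_genome, k = 13L) {
  if (k < 8L || k > 32L) stop("k must be in [8, 32]")
  lens <- nchar(query_genome)
  offsets <- cumsum(c(0L, unname(lens[-length(lens)])))
  names(offsets) <- names(query_genome)
  kmers <- character(0); gpos <- integer(0)
  for (i in seq_along(query_genome)) {
    L <- lens[i]
    if (L < k) next
    km <- substring(query_genome[[i]], 1:(L - k + 1L), k:L)
    keep <- !grepl("N", km, fixed = TRUE)
    kmers <- c(kmers, km[keep])
    gpos <- c(gpos, (which(keep) - 1L) + offsets[i])  # global 0-based
  }
  env <- list2env(split(gpos, kmers), envir = new.env(hash = TRUE, size = max(16L, length(kmers))))
  structure(list(k = as.integer(k), env = env, seq_ids = names(query_genome),
                 seq_len = unname(lens), offsets = unname(offsets),
                 genome = query_genome, total_len = sum(lens)),
            class = "kmer_index")
}

.global_to_local <- function(index, g) {
  i <- findInterval(g, index$offsets)
  list(seq = index$seq_ids[i], pos = g - index$offsets[i])
}

# collect seed hits of q against the index; returns data.frame(qoff, gpos)
.seed_hits <- function(q, index) {
  k <- index$k
  L <- nchar(q)
  if (L < k) return(NULL)
  km <- substring(q, 1:(L - k + 1L), k:L)
  found <- mget(km, envir = index$env, ifnotfound = list(NULL))
  nhit <- lengths(found)
  if (!sum(nhit)) return(NULL)
  data.frame(qoff = rep(0:(L - k), nhit), gpos = unlist(found, use.names = FALSE))
}

#' Map a reference intron to its best query-genome locus
#'
#' Seed-and-extend homology search: exact k-mer seeds against
#' [build_query_index()], seed clustering by diagonal, semiglobal extension
#' ([align_glocal()]) of the best candidate windows so the whole intron is
#' covered, Karlin-Altschul gating on bit
#' score and E-value, and an ambiguity flag when the runner-up locus scores
#' within `ambiguity_margin` of the best bit score (ambiguous introns are
#' excluded from ILP conversion downstream).
#'
#' @param intron_seq Intron sequence, coding orientation, length >= k.
#' @param index A `kmer_index` of the query genome.
#' @param min_bit Minimum bit score (the genome-scale production default is
#'   500; scale it down for small search spaces).
#' @param max_evalue Maximum E-value; "E-value 0" gates are represented as a
#'   small positive cutoff since exact zero only arises from underflow.
#' @param ambiguity_margin Runner-up bit score fraction above which the match
#'   is flagged ambiguous.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring.
#' @param lambda,K Karlin-Altschul parameters for the scoring scheme.
#' @return A list (`query_seq_id`, `query_start`, `query_end` 0-based
#'   half-open on the forward strand, `strand_rel` `"same"`/`"opposite"`,
#'   `raw_score`, `bit_score`, `e_value`, `identity_pct`, `ambiguous`,
#'   `query_seq` oriented to match the intron), or `NULL` when no candidate
#'   passes the gates.
#' @export
map_intron_to_query <- function(intron_seq, index, min_bit = 500, max_evalue = 1e-50,
                                ambiguity_margin = 0.95,
                                match = 1, mismatch = -2, gap_open = 5, gap_extend = 2,
                                lambda = 1.28, K = 0.46) {
  stopifnot(inherits(index, "kmer_index"))
  if (nchar(intron_seq) < index$k) return(NULL)
  pad <- 120L
  cands <- list()
  for (strand_rel in c("same", "opposite")) {
    q <- if (strand_rel == "same") intron_seq else .revcomp(intron_seq)
    hits <- .seed_hits(q, index)
    if (is.null(hits)) next
    diag <- hits$gpos - hits$qoff
    ord <- order(diag)
    diag <- diag[ord]; hits <- hits[ord, ]
    brk <- c(0L, which(diff(diag) > pad), nrow(hits))
    for (ci in seq_len(length(brk) - 1L)) {
      rows <- (brk[ci] + 1L):brk[ci + 1L]
      cands[[length(cands) + 1L]] <- list(strand_rel = strand_rel,
                                          n_seeds = length(unique(hits$qoff[rows])),
                                          gmin = min(hits$gpos[rows]),
                                          gmax = max(hits$gpos[rows]))
    }
  }
  if (!length(cands)) return(NULL)
  nseeds <- vapply(cands, `[[`, numeric(1), "n_seeds")
  # random k-mer collisions produce singleton clusters; skip extending them
  # whenever a better-supported cluster exists
  cands <- cands[nseeds >= min(max(nseeds), 2)]
  cands <- cands[order(-vapply(cands, `[[`, numeric(1), "n_seeds"))]
  cands <- utils::head(cands, 3L)

  results <- list()
  for (cd in cands) {
    loc <- .global_to_local(index, cd$gmin)
    sid <- loc$seq
    slen <- index$seq_len[match(sid, index$seq_ids)]
    wstart <- max(0L, loc$pos - pad)
    wend <- min(slen, (cd$gmax - index$offsets[match(sid, index$seq_ids)]) + index$k + pad)
    window <- substr(index$genome[[sid]], wstart + 1L, wend)
    q <- if (cd$strand_rel == "same") intron_seq else .revcomp(intron_seq)
    aln <- align_glocal(q, window, match, mismatch, gap_open, gap_extend)
    if (aln$aln_len == 0L) next
    qs <- wstart + aln$b_start
    qe <- wstart + aln$b_end
    bit <- karlin_bit_score(aln$score, lambda, K)
    slice <- substr(index$genome[[sid]], qs + 1L, qe)
    results[[length(results) + 1L]] <- list(
      query_seq_id = sid, query_start = qs, query_end = qe,
      strand_rel = cd$strand_rel, raw_score = aln$score, bit_score = bit,
      e_value = karlin_evalue(bit, nchar(intron_seq), index$total_len),
      identity_pct = 100 * aln$matches / aln$aln_len,
      query_seq = if (cd$strand_rel == "same") slice else .revcomp(slice))
  }
  if (!length(results)) return(NULL)
  ok <- vapply(results, function(r) r$bit_score >= min_bit && r$e_value <= max_evalue, logical(1))
  if (!any(ok)) return(NULL)
  surv <- results[ok]
  key <- order(-vapply(surv, `[[`, numeric(1), "raw_score"),
               vapply(surv, `[[`, character(1), "query_seq_id"),
               vapply(surv, `[[`, numeric(1), "query_start"))
  surv <- surv[key]
  best <- surv[[1L]]
  best$ambiguous <- FALSE
  if (length(surv) > 1L) {
    ru <- surv[[2L]]
    distinct <- !(ru$query_seq_id == best$query_seq_id &&
                  ru$query_start < best$query_end && best$query_start < ru$query_end)
    if (distinct && ru$bit_score >= ambiguity_margin * best$bit_score) best$ambiguous <- TRUE
  }
  best
}

#' Convert one ISM marker to an ILP marker
#'
#' An ISM converts to an ILP marker when its target intron carries at least
#' one InDel against the query genome, the homology match is unambiguous, and
#' the identical primer pair amplifies a single product from both genomes.
#' Fragment-length polymorphism is predicted from in-silico PCR on the two
#' genomes: `flp_net = |ref_amplicon - query_amplicon|` (what a gel
#' observes), `flp_gross` is the summed InDel length. Markers whose InDels
#' balance exactly (`flp_net == 0` despite `flp_gross > 0`) are returned with
#' `balanced = TRUE`; they are not gel-detectable ILP markers. The assay tier
#' is `"gel"` at >= 10 bp net polymorphism, `"sequencing"` below.
#'
#' @param ism One ISM marker row (from [design_genome_ism()]).
#' @param match Result of [map_intron_to_query()] for the target intron.
#' @param indels InDel calls from [align_and_call_indels()].
#' @param ref_genome,query_genome Named character vectors.
#' @param max_product In-silico PCR product cap, bases.
#' @return A one-row data frame, or a zero-row data frame carrying a
#'   `"reason"` attribute when conversion is refused (`"no_match"`,
#'   `"ambiguous_match"`, `"no_indel"`, `"nonunique_query_binding"`,
#'   `"no_ref_amplicon"`).
#' @export
convert_to_ilp <- function(ism, match, indels, ref_genome, query_genome,
                           max_product = 3000L) {
  refuse <- function(reason) {
    df <- data.frame(parent_ism_id = character(0), gene_id = character(0),
                     intron_ordinal = integer(0), seq_id = character(0),
                     fwd_pos = integer(0), rev_pos = integer(0),
                     ref_amp_len = integer(0), query_amp_len = integer(0),
                     flp_net = integer(0), flp_gross = integer(0),
                     n_indels = integer(0), assay_tier = character(0),
                     balanced = logical(0), stringsAsFactors = FALSE)
    attr(df, "reason") <- reason
    df
  }
  if (is.null(match)) return(refuse("no_match"))
  if (isTRUE(match$ambiguous)) return(refuse("ambiguous_match"))
  if (is.null(indels) || !nrow(indels)) return(refuse("no_indel"))
  if (is.data.frame(ism)) ism <- as.list(ism[1L, ])
  q_amp <- predict_amplicons(ism$fwd_seq, ism$rev_seq, query_genome, max_product)
  if (nrow(q_amp) != 1L) return(refuse("nonunique_query_binding"))
  r_amp <- predict_amplicons(ism$fwd_seq, ism$rev_seq, ref_genome, max_product)
  if (nrow(r_amp) != 1L) return(refuse("no_ref_amplicon"))
  flp_net <- abs(r_amp$length - q_amp$length)
  flp_gross <- sum(indels$length)
  data.frame(parent_ism_id = ism$marker_id, gene_id = ism$gene_id,
             intron_ordinal = ism$intron_ordinal, seq_id = ism$seq_id,
             fwd_pos = ism$fwd_pos, rev_pos = ism$rev_pos,
             ref_amp_len = r_amp$length, query_amp_len = q_amp$length,
             flp_net = flp_net, flp_gross = flp_gross,
             n_indels = nrow(indels),
             assay_tier = if (flp_net >= 10L) "gel" else "sequencing",
             balanced = flp_net == 0L,
             stringsAsFactors = FALSE)
}

# map a coding-orientation intron offset/length to reference chromosome
# coordinates and strand-correct alleles (for the VCF-like indel table)
.indel_genome_coords <- function(calls, intron) {
  if (!nrow(calls)) return(calls)
  if (intron$strand == "+") {
    calls$chrom_pos <- intron$start + calls$ref_pos
    calls$ref_allele <- calls$allele_ref
    calls$alt_allele <- calls$allele_query
  } else {
    span <- ifelse(calls$kind == "deletion", calls$length, 0L)
    calls$chrom_pos <- intron$end - calls$ref_pos - span
    calls$ref_allele <- .revcomp(calls$allele_ref)
    calls$alt_allele <- .revcomp(calls$allele_query)
  }
  calls
}

#' Convert a genome-wide ISM set to ILP markers
#'
#' For every ISM marker: locate the target intron in the query genome
#' ([map_intron_to_query()]), call InDels ([align_and_call_indels()]), and
#' convert ([convert_to_ilp()]). Converted markers receive `OsILP#####`
#' identifiers in chromosome-then-position order. Balanced-InDel markers
#' (net zero) go to a side table, and every refusal is logged with its
#' reason.
#'
#' @param ref_genome,query_genome Named character vectors.
#' @param models Named list of [gene_model] objects (reference annotation).
#' @param ism_markers Data frame from [design_genome_ism()].
#' @param min_bit,max_evalue,ambiguity_margin Homology gates
#'   ([map_intron_to_query()]).
#' @param k Seed k-mer size.
#' @param max_product In-silico PCR product cap.
#' @return List: `ilp` (marker data frame with `marker_id`), `indels`
#'   (VCF-like table: `CHROM`, `POS_1based`, `REF`, `ALT`, `marker_id`;
#'   deletions have `ALT = "-"`, insertions `REF = "-"`), `balanced` (side
#'   table), `log` (refusals with reasons).
#' @export
design_ilp <- function(ref_genome, models, ism_markers, query_genome,
                       min_bit = 500, max_evalue = 1e-50, ambiguity_margin = 0.95,
                       k = 13L, max_product = 3000L) {
  introns <- extract_all_introns(models, ref_genome)
  index <- build_query_index(query_genome, k)
  ilp_rows <- list(); indel_rows <- list(); log_rows <- list()
  for (i in seq_len(nrow(ism_markers))) {
    ism <- as.list(ism_markers[i, ])
    irow <- introns[introns$gene_id == ism$gene_id & introns$ordinal == ism$intron_ordinal, ]
    if (nrow(irow) != 1L) next
    irow <- as.list(irow[1L, ])
    mt <- map_intron_to_query(irow$sequence, index, min_bit, max_evalue, ambiguity_margin)
    calls <- if (!is.null(mt)) align_and_call_indels(irow$sequence, mt$query_seq)$indels else NULL
    conv <- convert_to_ilp(ism, mt, calls, ref_genome, query_genome, max_product)
    if (!nrow(conv)) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        marker_id = ism$marker_id, reason = attr(conv, "reason"), stringsAsFactors = FALSE)
      next
    }
    ilp_rows[[length(ilp_rows) + 1L]] <- conv
    cc <- .indel_genome_coords(calls, irow)
    indel_rows[[length(indel_rows) + 1L]] <- data.frame(
      CHROM = irow$seq_id, POS_1based = cc$chrom_pos + 1L,
      REF = ifelse(cc$kind == "deletion", cc$ref_allele, "-"),
      ALT = ifelse(cc$kind == "insertion", cc$alt_allele, "-"),
      marker_id = ism$marker_id, stringsAsFactors = FALSE)
  }
  empty_ilp <- data.frame(marker_id = character(0), parent_ism_id = character(0),
                          gene_id = character(0), intron_ordinal = integer(0),
                          seq_id = character(0), ref_amp_len = integer(0),
                          query_amp_len = integer(0), flp_net = integer(0),
                          flp_gross = integer(0), n_indels = integer(0),
                          assay_tier = character(0), stringsAsFactors = FALSE)
  if (!length(ilp_rows))
    return(list(ilp = empty_ilp, balanced = empty_ilp,
                indels = data.frame(CHROM = character(0), POS_1based = integer(0),
                                    REF = character(0), ALT = character(0),
                                    marker_id = character(0), stringsAsFactors = FALSE),
                log = if (length(log_rows)) do.call(rbind, log_rows) else
                  data.frame(marker_id = character(0), reason = character(0))))
  all_conv <- do.call(rbind, ilp_rows)
  balanced <- all_conv[all_conv$balanced, , drop = FALSE]
  ilp <- all_conv[!all_conv$balanced, , drop = FALSE]
  ilp <- assign_marker_ids(ilp, prefix = "OsILP")
  ilp$fwd_pos <- NULL; ilp$rev_pos <- NULL; ilp$balanced <- NULL
  rownames(balanced) <- NULL
  indels <- do.call(rbind, indel_rows)
  # keep only indel rows belonging to true (non-balanced) ILP markers
  indels_ilp <- indels[indels$marker_id %in% ilp$parent_ism_id, , drop = FALSE]
  id_map <- stats::setNames(ilp$marker_id, ilp$parent_ism_id)
  indels_ilp$marker_id <- unname(id_map[indels_ilp$marker_id])
  rownames(indels_ilp) <- NULL
  list(ilp = ilp, balanced = balanced, indels = indels_ilp,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(marker_id = character(0), reason = character(0)))
}

#' Write an ILP marker table as TSV
#'
#' @param ilp Data frame from [design_ilp()]`$ilp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ilp_tsv <- function(ilp, path) {
  cols <- c("marker_id", "parent_ism_id", "gene_id", "seq_id", "ref_amp_len",
            "query_amp_len", "flp_net", "flp_gross", "n_indels", "assay_tier")
  utils::write.table(ilp[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
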