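#' Genome-wide marker census
#'
#' Per-chromosome and overall marker counts, markers per gene and markers per
#' megabase. Accepts either a marker table (rows per marker with `seq_id` and
#' `gene_id`; genes-with-markers are counted as distinct `gene_id` per
#' chromosome) or a pre-tabulated count table (columns `seq_id`, `n_markers`,
#' `n_genes`, optional `chrom_len`), which is how printed study totals are
#' re-derived. Ratios are kept at full precision; the print method rounds to
#' one decimal as in published reports.
#'
#' @param markers Marker data frame, or a count table with an `n_markers`
#'   column.
#' @param gene_models Ignored when `markers` is a count table; otherwise an
#'   optional model list (interface completeness).
#' @param chrom_lengths Named vector of chromosome lengths in bases (optional;
#'   enables markers/Mb).
#' @return Data frame of class `marker_census`: one row per chromosome plus
#'   an `"overall"` row, with `n_markers`, `n_genes`, `markers_per_gene`,
#'   and `markers_per_mb` when lengths are known. The overall per-gene ratio
#'   is total markers over total genes-with-markers.
#' @export
marker_census <- function(markers, gene_models = NULL, chrom_lengths = NULL) {
  if ("n_markers" %in% names(markers)) {
    tab <- data.frame(seq_id = as.character(markers$seq_id),
                      n_markers = markers$n_markers,
                      n_genes = markers$n_genes, stringsAsFactors = FALSE)
    if ("chrom_len" %in% names(markers) && is.null(chrom_lengths))
      chrom_lengths <- stats::setNames(markers$chrom_len, markers$seq_id)
  } else {
    sp <- split(markers, markers$seq_id)
    tab <- data.frame(seq_id = names(sp),
                      n_markers = vapply(sp, nrow, integer(1)),
                      n_genes = vapply(sp, function(d) length(unique(d$gene_id)), integer(1)),
                      stringsAsFactors = FALSE)
  }
  tab$markers_per_gene <- ifelse(tab$n_genes > 0, tab$n_markers / tab$n_genes, NA_real_)
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[tab$seq_id])
    tab$chrom_len_mb <- len / 1e6
    tab$markers_per_mb <- tab$n_markers / tab$chrom_len_mb
  }
  overall <- data.frame(seq_id = "overall",
                        n_markers = sum(tab$n_markers),
                        n_genes = sum(tab$n_genes),
                        markers_per_gene = if (sum(tab$n_genes) > 0)
                          sum(tab$n_markers) / sum(tab$n_genes) else NA_real_,
                        stringsAsFactors = FALSE)
  if (!is.null(chrom_lengths)) {
    overall$chrom_len_mb <- sum(tab$chrom_len_mb)
    overall$markers_per_mb <- overall$n_markers / overall$chrom_len_mb
  }
  out <- rbind(tab, overall)
  rownames(out) <- NULL
  class(out) <- c("marker_census", "data.frame")
  out
}

#' @export
print.marker_census <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in c("markers_per_gene", "markers_per_mb"))
    if (cl %in% names(y)) y[[cl]] <- round(y[[cl]], 1)
  if ("chrom_len_mb" %in% names(y)) y$chrom_len_mb <- round(y$chrom_len_mb, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

.default_flp_bins <- function() {
  data.frame(label = c("1-4", "5-9", "10-49", "50-101", ">101"),
             lo = c(1, 5, 10, 50, 102), hi = c(4, 9, 49, 101, Inf),
             stringsAsFactors = FALSE)
}

#' Fragment-length polymorphism distribution
#'
#' Bins net fragment-length polymorphism sizes and reports per-bin counts and
#' percentages over all ILP markers, plus the mean FLP. Either raw `flp_net`
#' values or pre-tabulated per-bin counts (named by bin label, the printed-
#' table path) may be supplied.
#'
#' @param flp_net Integer vector of net FLP sizes in bases (>= 1), or `NULL`.
#' @param bins Data frame with `label`, `lo`, `hi` columns; default bins
#'   1-4, 5-9, 10-49, 50-101, >101 bp.
#' @param counts Named numeric vector of per-bin counts (alternative input).
#' @return Data frame `bin`, `count`, `pct` with attribute `mean_flp` (NA for
#'   counts-only input). Percentages are full precision; round for report.
#' @export
flp_distribution <- function(flp_net = NULL, bins = .default_flp_bins(), counts = NULL) {
  if (is.null(counts)) {
    if (is.null(flp_net)) flp_net <- integer(0)
    counts <- vapply(seq_len(nrow(bins)), function(i)
      sum(flp_net >= bins$lo[i] & flp_net <= bins$hi[i]), numeric(1))
    names(counts) <- bins$label
    mean_flp <- if (length(flp_net)) mean(flp_net) else NA_real_
  } else {
    counts <- counts[match(bins$label, names(counts))]
    counts[is.na(counts)] <- 0
    names(counts) <- bins$label
    mean_flp <- NA_real_
  }
  total <- sum(counts)
  out <- data.frame(bin = bins$label, count = as.numeric(counts),
                    pct = if (total > 0) 100 * counts / total else rep(0, nrow(bins)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mean_flp") <- mean_flp
  out
}

#' Marker amplification and polymorphism summary
#'
#' Amplification success is `amplified / tested`; polymorphism share is
#' `polymorphic / amplified` -- both as percentages, per marker class and
#' overall (column sums). The ordering `polymorphic <= amplified <= tested`
#' is enforced per class.
#'
#' @param n_tested,n_amplified,n_polymorphic Integer vectors, one entry per
#'   marker class.
#' @param class Class labels (default `class_1`, ...).
#' @return Data frame with per-class rows and an `"overall"` row:
#'   `amplification_pct`, `polymorphism_pct` at full precision.
#' @export
validation_summary <- function(n_tested, n_amplified, n_polymorphic,
                               class = paste0("class_", seq_along(n_tested))) {
  stopifnot(length(n_tested) == length(n_amplified),
            length(n_tested) == length(n_polymorphic))
  if (any(n_amplified > n_tested) || any(n_polymorphic > n_amplified))
    stop("require n_polymorphic <= n_amplified <= n_tested in every class")
  out <- data.frame(class = c(class, "overall"),
                    n_tested = c(n_tested, sum(n_tested)),
                    n_amplified = c(n_amplified, sum(n_amplified)),
                    n_polymorphic = c(n_polymorphic, sum(n_polymorphic)),
                    stringsAsFactors = FALSE)
  out$amplification_pct <- 100 * out$n_amplified / out$n_tested
  out$polymorphism_pct <- 100 * out$n_polymorphic / out$n_amplified
  rownames(out) <- NULL
  out
}

#' Genetic-map saturation statistics
#'
#' Mean inter-marker distance per linkage group and overall, computed as map
#' length over marker count (`length / markers`, the convention that
#' reproduces published per-chromosome saturation tables), with the overall
#' mean as total length over total markers.
#'
#' @param map_table Data frame with columns `chromosome`, `n_markers`,
#'   `map_length_cM`.
#' @return `map_table` with a `mean_intermarker_cM` column and a `"Total"`
#'   row of column sums; distances at full precision (round to 2 decimals
#'   for report). Rows with zero markers get `NA`.
#' @export
map_saturation <- function(map_table) {
  stopifnot(all(c("chromosome", "n_markers", "map_length_cM") %in% names(map_table)))
  tab <- map_table
  tab$mean_intermarker_cM <- ifelse(tab$n_markers >= 1,
                                    tab$map_length_cM / tab$n_markers, NA_real_)
  total <- data.frame(chromosome = "Total",
                      n_markers = sum(tab$n_markers),
                      map_length_cM = sum(tab$map_length_cM),
                      stringsAsFactors = FALSE)
  total$mean_intermarker_cM <- if (total$n_markers >= 1)
    total$map_length_cM / total$n_markers else NA_real_
  out <- rbind(tab[, names(total)], total)
  rownames(out) <- NULL
  out
}

#' Printed summary tables of the rice ISM/ILP marker study
#'
#' Accessors for the plain-text tables shipped with the package: the
#' genome-wide marker/validation counts and the IR 64 x Sonasal linkage-map
#' table, used to re-derive the published summary ratios.
#'
#' @return `study_marker_counts()`: a named list of integer counts.
#'   `study_linkage_map()`: a data frame with `chromosome`, `n_markers`,
#'   `map_length_cM`.
#' @export
study_marker_counts <- function() {
  path <- system.file("extdata", "rice_study_counts.tsv", package = "ismilp", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.list(tab$value), tab$quantity)
}

#' @rdname study_marker_counts
#' @export
study_linkage_map <- function() {
  path <- system.file("extdata", "linkage_map_ir64_sonasal.tsv", package = "ismilp",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
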