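#' Run the full ISM -> ILP marker pipeline
#'
#' Convenience wrapper chaining genome-wide ISM design
#' ([design_genome_ism()]) and ILP conversion ([design_ilp()]) on a
#' reference/query genome pair.
#'
#' @param ref_genome,query_genome Named character vectors.
#' @param models Named list of [gene_model] objects (reference annotation).
#' @param constraints A [design_constraints()] object.
#' @param per_gene Maximum ISM markers per gene (`Inf` = every designable
#'   intron; the cataloguing policy of multiple markers per gene is 4).
#' @param mode `"genomic"` or `"expression"` primer design mode.
#' @param min_bit,max_evalue,ambiguity_margin Homology gates; the genome-
#'   scale production defaults are bit >= 500 and E <= 1e-50. Scale them to
#'   the search space at hand.
#' @param k Seed k-mer size for the query index.
#' @param max_product In-silico PCR product cap, bases.
#' @return List: `ism` (marker table), `ilp`, `balanced`, `indels`, `log`
#'   (see [design_ilp()]).
#' @export
run_marker_pipeline <- function(ref_genome, models, query_genome,
                                constraints = design_constraints(),
                                per_gene = 4L, mode = "genomic",
                                min_bit = 500, max_evalue = 1e-50,
                                ambiguity_margin = 0.95,
                                k = 13L, max_product = 3000L) {
  ism <- design_genome_ism(ref_genome, models, constraints, per_gene, mode,
                           check_uniqueness = TRUE, max_product = max_product)
  conv <- design_ilp(ref_genome, models, ism, query_genome,
                     min_bit = min_bit, max_evalue = max_evalue,
                     ambiguity_margin = ambiguity_margin, k = k,
                     max_product = max_product)
  c(list(ism = ism), conv)
}
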