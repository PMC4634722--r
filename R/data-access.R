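#' Curated FnrL binding sites of Rhodobacter capsulatus
#'
#' The ChIP-supported, consensus-bearing recognition sequences of directly
#' regulated genes in the Rhodobacter capsulatus FnrL regulon, shipped as
#' a plain TSV under `inst/extdata`. Useful as a realistic input for
#' [build_pwm()], [consensus_string()] and [match_iupac()]: the site
#' family shows the invariant TG / CA core at positions 2-3 and 12-13
#' with a degenerate (T/C/A) first position.
#'
#' @return data.frame with columns `locus_id`, `gene_name`,
#'   `recognition_sequence`, `location` (`a` coding region / `b` upstream
#'   intergenic), `enrichment`, `regulation` (+/-), `fold_change`, `cog`.
#' @export
#' @examples
#' sites <- fnrl_example_sites()
#' p <- build_pwm(sites$recognition_sequence, pseudocount = 0)
#' format(consensus_string(p, invariant_thresh = 0.99,
#'                         include_thresh = 0.20))
fnrl_example_sites <- function() {
  path <- system.file("extdata", "fnrl_sites_rcapsulatus.tsv",
                      package = "regulonscan", mustWork = TRUE)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
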