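#' Methylation-specific PCR assay definition
#'
#' Two primer pairs for the same amplicon of bisulfite-converted template:
#' the U pair matches the fully converted (unmethylated) sequence and the M
#' pair the methylation-protected sequence. Forward primers are given on the
#' converted sense strand, reverse primers 5'->3' on the opposite strand.
#'
#' @param primers Data.frame with columns `name`, `sequence`, `strand`
#'   (`+`/`-`), `reaction` (`U`/`M`/`outer`); the shared primer-table dialect.
#' @param amplicon_region Region name the assay targets (default `"core"`).
#' @return Object of class `msp_assay`.
#' @export
msp_assay <- function(primers, amplicon_region = "core") {
  needed <- c("name", "sequence", "strand", "reaction")
  if (!all(needed %in% names(primers)))
    stop("primer table needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  for (rx in c("U", "M")) {
    sub <- primers[primers$reaction == rx, ]
    if (sum(sub$strand == "+") < 1L || sum(sub$strand == "-") < 1L)
      stop(sprintf("reaction %s needs a forward (+) and a reverse (-) primer", rx),
           call. = FALSE)
  }
  structure(list(primers = primers, amplicon_region = amplicon_region),
            class = "msp_assay")
}

#' Design U/M primer pairs against a promoter reference
#'
#' Derives methylation-specific and unmethylated-specific primer pairs from
#' the reference itself: the forward primer is the first window of the
#' amplicon region containing at least `min_cpg` CpG sites, the reverse
#' primer the last, each taken from the fully converted (U) or
#' methylation-protected (M) in-silico bisulfite sequence. Useful for
#' simulation and for the bundled synthetic reference; real assays supply
#' their published primer table instead.
#'
#' @param ref A [promoter_reference()].
#' @param region Amplicon region (default `"core"`).
#' @param primer_length Primer length in bases (default 22).
#' @param min_cpg Minimum CpG sites a primer must cover (default 2).
#' @return An [msp_assay()].
#' @export
design_msp_primers <- function(ref, region = "core", primer_length = 22,
                               min_cpg = 2) {
  sites <- enumerate_cpg_sites(ref, region)
  if (nrow(sites) < 2 * min_cpg)
    stop("amplicon region has too few CpG sites for primer design", call. = FALSE)
  r <- ref$regions[[region]]
  lo <- tss_to_index(ref, r[1])
  hi <- tss_to_index(ref, region_last_position(r))
  conv_u <- bisulfite_convert(ref$sequence)              # all C -> T
  conv_m <- bisulfite_convert(ref$sequence,
                              full_methylation_state(ref))  # CpG C protected
  covers <- function(start) sum(sites$index >= start &
                                  sites$index <= start + primer_length - 1L)
  starts <- lo:(hi - primer_length + 1L)
  ok <- starts[vapply(starts, covers, integer(1)) >= min_cpg]
  if (length(ok) == 0L) stop("no primer window covers enough CpG sites", call. = FALSE)
  fwd_at <- ok[1]; rev_at <- ok[length(ok)]
  if (rev_at <= fwd_at + primer_length)
    stop("amplicon too short for non-overlapping primers", call. = FALSE)
  win <- function(conv, at) substr(conv, at, at + primer_length - 1L)
  primers <- data.frame(
    name = c("U-fwd", "U-rev", "M-fwd", "M-rev"),
    sequence = c(win(conv_u, fwd_at), reverse_complement(win(conv_u, rev_at)),
                 win(conv_m, fwd_at), reverse_complement(win(conv_m, rev_at))),
    strand = c("+", "-", "+", "-"),
    reaction = c("U", "U", "M", "M"),
    stringsAsFactors = FALSE
  )
  msp_assay(primers, region)
}

# methylation_state with m = 1 at every CpG of the whole sequence
full_methylation_state <- function(ref) {
  sites <- enumerate_cpg_sites(ref, "all")
  stats::setNames(rep(1, nrow(sites)), sites$index)
}

#' Classify one case by in-silico MSP
#'
#' Binarizes the latent methylation state (protected when `m >=
#' binarize_threshold`; MSP is qualitative), bisulfite-converts the template
#' at efficiency 1, and scores each reaction as amplified when both of its
#' primers match the converted template with zero mismatches (forward on the
#' template, reverse on its reverse complement) in amplifiable orientation.
#' Core-promoter status is methylated iff the M reaction amplifies; a case
#' where neither reaction amplifies is invalid.
#'
#' @param state Numeric methylation fractions named by sequence position of
#'   the CpG cytosines (at least those of the amplicon region), e.g. a
#'   [methylation_state()].
#' @param ref A [promoter_reference()].
#' @param assay An [msp_assay()].
#' @param binarize_threshold Protection threshold on `m` (default 0.5).
#' @param max_mismatches Mismatch tolerance (default 0).
#' @param case_id Optional identifier carried into the result.
#' @return List of class `msp_result`: `case_id`, `amplified_U`,
#'   `amplified_M`, `core_pm_status` in `{"methylated", "unmethylated",
#'   "invalid"}`.
#' @export
msp_classify <- function(state, ref, assay, binarize_threshold = 0.5,
                         max_mismatches = 0, case_id = NA_character_) {
  stopifnot(inherits(ref, "promoter_reference"), inherits(assay, "msp_assay"))
  amp_sites <- enumerate_cpg_sites(ref, assay$amplicon_region)
  pos <- as.integer(names(state))
  if (!all(amp_sites$index %in% pos))
    stop("`state` must cover every CpG site of the amplicon region", call. = FALSE)
  binary <- stats::setNames(as.numeric(as.numeric(state) >= binarize_threshold),
                            names(state))
  template <- bisulfite_convert(ref$sequence, binary)
  template_rc <- reverse_complement(template)
  amplifies <- function(reaction) {
    pr <- assay$primers[assay$primers$reaction == reaction, ]
    fwd <- pr[pr$strand == "+", ][1, ]
    rev <- pr[pr$strand == "-", ][1, ]
    f <- primer_matches(fwd$sequence, template, max_mismatches)
    r <- primer_matches(rev$sequence, template_rc, max_mismatches)
    if (!f$match || !r$match) return(FALSE)
    # reverse primer 3' end must sit downstream of the forward primer
    rev_start_on_template <- nchar(template) - (r$position + nchar(rev$sequence) - 1L) + 1L
    rev_start_on_template > f$position
  }
  u <- amplifies("U"); m <- amplifies("M")
  status <- if (m) "methylated" else if (u) "unmethylated" else "invalid"
  structure(list(case_id = case_id, amplified_U = u, amplified_M = m,
                 core_pm_status = status),
            class = "msp_result")
}

#' Core-promoter methylation frequency
#'
#' Fraction of MSP-methylated cases among valid results, with the count
#' breakdown (e.g. 8 methylated of 326 valid = 2.5%).
#'
#' @param results List of `msp_result` objects, or a data.frame with a
#'   `core_pm_status` column.
#' @return List: `n_valid`, `n_methylated`, `n_invalid`, `fraction`,
#'   `percent` (rounded to one decimal).
#' @export
core_pm_frequency <- function(results) {
  status <- if (is.data.frame(results)) {
    as.character(results$core_pm_status)
  } else {
    vapply(results, function(r) r$core_pm_status, character(1))
  }
  valid <- status != "invalid"
  if (!any(valid)) stop("no valid MSP results", call. = FALSE)
  n_meth <- sum(status == "methylated")
  frac <- n_meth / sum(valid)
  list(n_valid = sum(valid), n_methylated = n_meth,
       n_invalid = sum(!valid), fraction = frac,
       percent = round(100 * frac, 1))
}

#' Read a primer table (TSV)
#'
#' Columns: `name`, `sequence`, `strand` (`+`/`-`), `reaction` (`U`/`M`/
#' `outer`).
#'
#' @param path TSV file path.
#' @return Data.frame in the shared primer dialect.
#' @export
read_primer_tsv <- function(path) {
  pr <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "sequence", "strand", "reaction")
  if (!all(needed %in% names(pr)))
    stop("primer TSV needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  pr$sequence <- toupper(pr$sequence)
  pr
}

#' Write a primer table (TSV)
#' @param primers Primer data.frame (or an `msp_assay`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_tsv <- function(primers, path) {
  if (inherits(primers, "msp_assay")) primers <- primers$primers
  utils::write.table(primers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
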