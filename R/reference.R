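#' Default CEBPA promoter regions
#'
#' The three functional promoter regions, in signed TSS-relative coordinates
#' with no position 0 and half-open intervals `[start, end)`: the distal
#' region (-1423 to -1121), the proximal region (-1121 to -896) and the core
#' region (-141 to +103). The distal boundary is configurable because the
#' literature reports both -1422 and -1423; -1423 is the default.
#'
#' @return Named list of length-2 integer vectors `c(start, end)`.
#' @export
default_promoter_regions <- function() {
  list(
    distal   = c(-1423L, -1121L),
    proximal = c(-1121L, -896L),
    core     = c(-141L, 103L)
  )
}

#' Construct a promoter reference
#'
#' Holds a sense-strand promoter sequence together with the position of the
#' transcription start site (+1) and a set of named analysis regions in
#' TSS-relative coordinates. All downstream analysis (CpG enumeration,
#' bisulfite conversion, MSP) works on this single strand.
#'
#' @param sequence Uppercase DNA string (A/C/G/T/N only).
#' @param tss_offset 1-based index of the +1 base within `sequence`.
#' @param regions Named list of `c(start, end)` TSS-relative half-open
#'   intervals; defaults to [default_promoter_regions()].
#' @return An object of class `promoter_reference`.
#' @export
promoter_reference <- function(sequence, tss_offset,
                               regions = default_promoter_regions()) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("`sequence` may contain only A, C, G, T, N", call. = FALSE)
  n <- nchar(sequence)
  stopifnot_scalar_number(tss_offset, "tss_offset", 1, n)
  tss_offset <- as.integer(tss_offset)
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("`regions` must be a named list", call. = FALSE)
  ref <- structure(
    list(sequence = sequence, tss_offset = tss_offset, regions = regions),
    class = "promoter_reference"
  )
  for (rn in names(regions)) {
    r <- regions[[rn]]
    if (length(r) != 2L || r[1] >= r[2] || r[1] == 0)
      stop(sprintf("region '%s' must be c(start, end) with start < end", rn),
           call. = FALSE)
    idx <- tss_to_index(ref, c(r[1], region_last_position(r)))
    if (any(idx < 1L) || any(idx > n))
      stop(sprintf("region '%s' lies outside the sequence", rn), call. = FALSE)
  }
  ref
}

# last TSS-relative position inside half-open [start, end), skipping 0
region_last_position <- function(r) {
  p <- r[2] - 1L
  if (p == 0L) p <- -1L
  p
}

#' Convert TSS-relative positions to string indices
#'
#' Positions are signed with no 0: -1 is the base immediately upstream of +1.
#'
#' @param ref A [promoter_reference()].
#' @param positions Vector of signed TSS-relative positions (no 0).
#' @return Integer vector of 1-based indices into `ref$sequence`.
#' @export
tss_to_index <- function(ref, positions) {
  if (any(positions == 0)) stop("TSS-relative position 0 does not exist", call. = FALSE)
  as.integer(ref$tss_offset + positions - (positions > 0))
}

#' Convert string indices to TSS-relative positions
#' @param ref A [promoter_reference()].
#' @param indices 1-based indices into `ref$sequence`.
#' @return Signed TSS-relative positions (no 0).
#' @export
index_to_tss <- function(ref, indices) {
  p <- as.integer(indices - ref$tss_offset)
  p + (p >= 0L)
}

#' @export
print.promoter_reference <- function(x, ...) {
  cat(sprintf("promoter_reference: %d bp, TSS at index %d\n",
              nchar(x$sequence), x$tss_offset))
  for (rn in names(x$regions)) {
    r <- x$regions[[rn]]
    sites <- tryCatch(nrow(enumerate_cpg_sites(x, rn)), error = function(e) NA)
    cat(sprintf("  %-9s [%+d, %+d)  %s CpG sites\n", rn, r[1], r[2], sites))
  }
  invisible(x)
}

#' Enumerate CpG dinucleotides in a promoter region
#'
#' Scans the sense strand for "CG" dimers whose C falls inside the half-open
#' region; the site position is the position of the C. "N" bases never form
#' CpG sites. The distal CEBPA region carries 24 such sites and the proximal
#' region 20 in the design this package models.
#'
#' @param ref A [promoter_reference()].
#' @param region Region name defined on `ref`, or `"all"` for the whole
#'   sequence.
#' @return A data.frame with columns `position` (TSS-relative position of the
#'   C), `index` (string index), `region`, `index_in_region` (0-based, 5'->3').
#' @export
enumerate_cpg_sites <- function(ref, region) {
  stopifnot(inherits(ref, "promoter_reference"))
  n <- nchar(ref$sequence)
  if (identical(region, "all")) {
    lo <- 1L; hi <- n
  } else {
    if (!region %in% names(ref$regions))
      stop(sprintf("unknown region '%s'", region), call. = FALSE)
    r <- ref$regions[[region]]
    lo <- tss_to_index(ref, r[1])
    hi <- tss_to_index(ref, region_last_position(r))
  }
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  # C inside [lo, hi], G may be the next base even past the region boundary
  cand <- lo:hi
  cand <- cand[cand < n]
  hit <- cand[chars[cand] == "C" & chars[cand + 1L] == "G"]
  data.frame(
    position = index_to_tss(ref, hit),
    index = hit,
    region = rep(if (identical(region, "all")) "all" else region,
                 length(hit)),
    index_in_region = seq_along(hit) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Methylation state for a set of CpG sites
#'
#' A latent per-site methylation fraction in `[0, 1]`, indexed by the CpG
#' sites of one region of a reference. Used as the ground truth for in-silico
#' bisulfite conversion and for simulation.
#'
#' @param ref A [promoter_reference()].
#' @param region Region name (or `"all"`).
#' @param m Numeric vector of methylation fractions, one per CpG site of the
#'   region in 5'->3' order.
#' @return Object of class `methylation_state`: numeric vector named by
#'   string index, with the site table as attribute `sites`.
#' @export
methylation_state <- function(ref, region, m) {
  sites <- enumerate_cpg_sites(ref, region)
  if (length(m) != nrow(sites))
    stop(sprintf("`m` must have one value per CpG site (%d expected, %d given)",
                 nrow(sites), length(m)), call. = FALSE)
  if (any(is.na(m)) || any(m < 0) || any(m > 1))
    stop("methylation fractions must lie in [0, 1]", call. = FALSE)
  structure(stats::setNames(as.numeric(m), sites$index),
            sites = sites, class = "methylation_state")
}

#' In-silico bisulfite conversion
#'
#' Converts unmethylated cytosines to thymine the way bisulfite treatment
#' followed by PCR reads them out: every C outside a CpG context converts
#' with probability `conversion_efficiency`; the C of CpG site i converts
#' with probability `conversion_efficiency * (1 - m_i)`. With efficiency 1
#' and binary methylation the output is deterministic.
#'
#' @param sequence DNA string (sense strand).
#' @param state Optional numeric vector of methylation fractions named by the
#'   1-based positions of CpG cytosines (e.g. a [methylation_state()]);
#'   `NULL` treats every CpG as unmethylated.
#' @param conversion_efficiency Fraction in `[0, 1]`; default 1.
#' @param seed Optional integer seed driving the stochastic conversion.
#' @return Converted DNA string of identical length.
#' @export
bisulfite_convert <- function(sequence, state = NULL,
                              conversion_efficiency = 1, seed = NULL) {
  stopifnot_scalar_number(conversion_efficiency, "conversion_efficiency", 0, 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  is_c <- chars == "C"
  in_cpg <- is_c & c(chars[-1] == "G", FALSE)
  m <- numeric(n)
  if (!is.null(state)) {
    pos <- as.integer(names(state))
    if (is.null(names(state)) || any(is.na(pos)))
      stop("`state` must be named by sequence positions", call. = FALSE)
    if (any(pos < 1L | pos > n) || any(!in_cpg[pos]))
      stop("`state` positions must be CpG cytosines of `sequence`", call. = FALSE)
    m[pos] <- as.numeric(state)
  }
  p_convert <- ifelse(in_cpg, conversion_efficiency * (1 - m),
                      conversion_efficiency)
  p_convert[!is_c] <- 0
  out <- chars
  if (conversion_efficiency == 1 && all(m[in_cpg] %in% c(0, 1))) {
    out[is_c & p_convert == 1] <- "T"
  } else {
    draws <- with_seed(seed, stats::runif(n))
    out[is_c & draws < p_convert] <- "T"
  }
  paste(out, collapse = "")
}

#' Match a primer against a template by sliding-window comparison
#'
#' Exact per-base comparison of the primer against every window of the
#' template on the given strand; reports whether some window has at most
#' `max_mismatches` mismatches, ties broken by the leftmost position.
#'
#' @param primer Primer sequence (5'->3' on the template strand).
#' @param template Template sequence.
#' @param max_mismatches Non-negative integer; default 0.
#' @return List with `match` (logical), `position` (1-based leftmost best
#'   start, NA when no window qualifies) and `mismatches` (count at that
#'   position).
#' @export
primer_matches <- function(primer, template, max_mismatches = 0) {
  if (nchar(primer) == 0L || nchar(template) == 0L)
    stop("empty primer or template", call. = FALSE)
  k <- nchar(primer); n <- nchar(template)
  if (k > n) stop("primer longer than template", call. = FALSE)
  p <- utf8ToInt(toupper(primer))
  t <- utf8ToInt(toupper(template))
  best_pos <- NA_integer_; best_mm <- Inf
  for (i in seq_len(n - k + 1L)) {
    mm <- sum(t[i:(i + k - 1L)] != p)
    if (mm < best_mm) { best_mm <- mm; best_pos <- i }
    if (best_mm == 0L) break
  }
  list(match = best_mm <= max_mismatches, position = best_pos,
       mismatches = as.integer(best_mm))
}

#' Reverse complement of a DNA string
#' @param x DNA string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a promoter reference from a single-record FASTA file
#'
#' @param path FASTA file with exactly one record.
#' @param tss_offset 1-based index of the +1 base.
#' @param regions Region list as in [promoter_reference()].
#' @return A `promoter_reference`.
#' @export
read_promoter_fasta <- function(path, tss_offset,
                                regions = default_promoter_regions()) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("expected a single-record FASTA file", call. = FALSE)
  promoter_reference(as.character(set[[1]]), tss_offset, regions)
}

#' Write a promoter reference to FASTA
#' @param ref A `promoter_reference`.
#' @param path Output path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(ref, path, name = "promoter") {
  set <- Biostrings::DNAStringSet(ref$sequence)
  names(set) <- sprintf("%s tss_offset=%d", name, ref$tss_offset)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Deterministic synthetic promoter reference
#'
#' Builds a synthetic sense-strand promoter whose region geometry matches the
#' CEBPA design modelled by this package: exactly 24 CpG dinucleotides in the
#' distal region (-1423 to -1121), 20 in the proximal region (-1121 to -896)
#' and 8 in the core region (-141 to +103, clustered at the region ends the
#' way MSP primers require), on a CpG-free background. It is a
#' synthetic stand-in for the (user-supplied) genomic CEBPA promoter sequence
#' and is fully deterministic: no RNG is consumed.
#'
#' @param upstream Bases upstream of the TSS to cover (default 1500).
#' @param downstream Bases from +1 onwards (default 150).
#' @return A `promoter_reference`.
#' @export
synthetic_promoter_reference <- function(upstream = 1500, downstream = 150) {
  stopifnot(upstream >= 1423, downstream >= 103)
  n <- upstream + downstream
  # 16-mer with no CG dimer, also CG-free across junctions (ends G|A)
  unit <- "ACTTAGATCATGATTG"
  seq <- substr(strrep(unit, ceiling(n / nchar(unit))), 1, n)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  tss <- upstream + 1L
  ref_coords <- function(p) tss + p - (p > 0)  # TSS-relative -> index
  plant <- function(chars, start, end, count) {
    lo <- ref_coords(start); hi <- ref_coords(end - 1L) - 1L
    at <- as.integer(round(seq(lo, hi, length.out = count)))
    stopifnot(all(diff(at) >= 2L))
    chars[at] <- "C"; chars[at + 1L] <- "G"
    chars
  }
  plant_at <- function(chars, positions) {
    at <- ref_coords(positions)
    stopifnot(all(diff(sort(at)) >= 2L))
    chars[at] <- "C"; chars[at + 1L] <- "G"
    chars
  }
  chars <- plant(chars, -1423L, -1121L, 24L)
  chars <- plant(chars, -1121L, -896L, 20L)
  # core CpGs clustered at both amplicon ends so U/M primers each cover >= 2
  chars <- plant_at(chars, c(-141L, -133L, -125L, -117L, 75L, 83L, 91L, 99L))
  promoter_reference(paste(chars, collapse = ""), tss)
}
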