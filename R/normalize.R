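#' Normalize a VCF allele pair to the ANNOVAR variant description convention
#'
#' Converts a VCF-dialect record (1-based position, explicit anchor bases)
#' into the 1-based inclusive (contig, start, end, ref, alt) key used by
#' ANNOVAR variant lists, with "-" standing for the absent allele of an
#' indel. The shared leading context base(s) are stripped before
#' classifying the event:
#' \itemize{
#'   \item SNV: start = end = pos, both alleles length 1.
#'   \item deletion of k bases: start = pos + 1, end = pos + k, alt = "-".
#'   \item insertion after pos: start = end = pos, ref = "-".
#'   \item block substitution: start..end spans the replaced reference bases.
#' }
#'
#' @param contig chromosome name; harmonized to the configured naming
#'   convention ("chr"-prefixed by default).
#' @param pos 1-based VCF position.
#' @param ref,alt VCF allele strings (multi-allelic records must already be
#'   split, one alt per call).
#' @param chrPrefix logical; normalize contig names to carry a "chr" prefix.
#' @return data.frame with one row: key, contig, start, end, ref, alt.
#' @examples
#' normalizeVariant("1", 100, "A", "G")     # SNV
#' normalizeVariant("1", 100, "AT", "A")    # deletion -> 101..101 T/-
#' normalizeVariant("1", 100, "A", "AGG")   # insertion -> 100..100 -/GG
#' @export
normalizeVariant <- function(contig, pos, ref, alt, chrPrefix = TRUE) {
    stopifnot(length(contig) == 1, length(pos) == 1,
              length(ref) == 1, length(alt) == 1)
    ref <- toupper(as.character(ref))
    alt <- toupper(as.character(alt))
    pos <- as.integer(pos)
    if (!nzchar(ref) || !nzchar(alt))
        stop("empty allele string")
    if (identical(ref, alt))
        stop("ref and alt are identical: not a variant")
    if (grepl("[<>\\[\\]]", alt) || alt == "*" || grepl("[<>\\[\\]]", ref))
        stop("unsupported allele (symbolic or breakend): ", alt)
    if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt))
        stop("unsupported allele characters in ", ref, "/", alt)
    contig <- normalizeContig(contig, chrPrefix)
    # strip shared leading context bases
    r <- strsplit(ref, "")[[1]]
    a <- strsplit(alt, "")[[1]]
    nshared <- 0L
    while (nshared < length(r) && nshared < length(a) &&
           r[nshared + 1L] == a[nshared + 1L])
        nshared <- nshared + 1L
    pos <- pos + nshared
    if (nshared > 0L) {
        r <- r[-seq_len(nshared)]
        a <- a[-seq_len(nshared)]
    }
    if (length(r) == 0L) {           # insertion after pos - 1
        start <- pos - 1L; end <- pos - 1L
        refOut <- "-"; altOut <- paste(a, collapse = "")
    } else if (length(a) == 0L) {    # deletion of the remaining ref bases
        start <- pos; end <- pos + length(r) - 1L
        refOut <- paste(r, collapse = ""); altOut <- "-"
    } else {                         # SNV or block substitution
        start <- pos; end <- pos + length(r) - 1L
        refOut <- paste(r, collapse = ""); altOut <- paste(a, collapse = "")
    }
    data.frame(key = variantKeyString(contig, start, end, refOut, altOut),
               contig = contig, start = start, end = end,
               ref = refOut, alt = altOut, stringsAsFactors = FALSE)
}

#' @rdname normalizeVariant
#' @export
normalizeContig <- function(contig, chrPrefix = TRUE) {
    contig <- as.character(contig)
    has <- grepl("^chr", contig, ignore.case = TRUE)
    bare <- sub("^chr", "", contig, ignore.case = TRUE)
    bare[bare == "MT"] <- "M"
    if (chrPrefix) paste0("chr", bare) else bare
}

#' Canonical string form of a variant key
#'
#' @param contig,start,end,ref,alt key fields (ANNOVAR convention).
#' @return character, "contig:start-end:ref>alt".
#' @export
variantKeyString <- function(contig, start, end, ref, alt) {
    sprintf("%s:%d-%d:%s>%s", contig, as.integer(start), as.integer(end),
            ref, alt)
}

# Parse a key string back into its fields (inverse of variantKeyString).
parseKeyString <- function(key) {
    m <- regmatches(key, regexec("^([^:]+):(\\d+)-(\\d+):([^>]+)>(.+)$", key))
    bad <- vapply(m, length, integer(1)) != 6L
    if (any(bad)) stop("malformed variant key: ", key[bad][1])
    data.frame(key = key,
               contig = vapply(m, `[`, "", 2L),
               start = as.integer(vapply(m, `[`, "", 3L)),
               end = as.integer(vapply(m, `[`, "", 4L)),
               ref = vapply(m, `[`, "", 5L),
               alt = vapply(m, `[`, "", 6L), stringsAsFactors = FALSE)
}
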