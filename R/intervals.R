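# Internal interval arithmetic.  All user-facing coordinates in this package
# are 0-based half-open; IRanges (1-based closed) is used only inside these
# helpers, converting at the boundary.

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
.msgf  <- function(...) message(sprintf(...))

# round half away from zero (so 67.92 -> 68, 92.34 -> 92, -0.5 -> -1)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(round(start)) + 1L,
                   end   = as.integer(round(end)))
}

# logical: does interval i of (chrom, start, end) overlap any target interval?
.overlaps_any <- function(chrom, start, end, t_chrom, t_start, t_end) {
  out <- logical(length(chrom))
  if (!length(t_chrom) || !length(chrom)) return(out)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    j <- which(t_chrom == ch)
    if (!length(j)) next
    out[i] <- IRanges::overlapsAny(.ir(start[i], end[i]),
                                   .ir(t_start[j], t_end[j]))
  }
  out
}

# distance between two 0-based half-open intervals (0 if they overlap or abut)
.interval_distance <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Normalize chromosome naming
#'
#' Mixed-source hg19 resources differ in whether they carry a `"chr"`
#' prefix.  Names are taken verbatim by default; `style = "strip"` removes
#' the prefix, `style = "add"` ensures it is present.
#'
#' @param x character vector of chromosome names.
#' @param style one of `"asis"`, `"strip"`, `"add"`.
#' @return character vector of normalized names.
#' @examples
#' normalize_chrom(c("chr1", "2"), "add")
#' @export
normalize_chrom <- function(x, style = c("asis", "strip", "add")) {
  style <- match.arg(style)
  switch(style,
         asis  = x,
         strip = sub("^chr", "", x),
         add   = ifelse(grepl("^chr", x), x, paste0("chr", x)))
}
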