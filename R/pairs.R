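#' Identify the standard root pairs from channel metadata
#'
#' Finds the two pairs the analysis tracks: the bilateral flexor pair
#' (the first left/right pair of flexor-dominated roots, ordered
#' right-then-left) and the ipsilateral flexor-extensor pair (a flexor
#' and an extensor root on the same side, flexor first). Errors when a
#' pair cannot be formed.
#'
#' @param channels List of [channel_meta()] objects.
#' @return Named list of 2-element integer index vectors
#'   (`bilateral_flexor`, `ipsilateral_flexor_extensor`).
#' @export
find_pairs <- function(channels) {
  dom <- vapply(channels, `[[`, character(1), "dominance")
  side <- vapply(channels, `[[`, character(1), "side")
  fr <- which(dom == "flexor" & side == "right")
  fl <- which(dom == "flexor" & side == "left")
  if (!length(fr) || !length(fl)) {
    stop("cannot form the bilateral flexor pair: need flexor-dominated ",
         "roots on both sides")
  }
  bil <- c(fr[1], fl[1])
  ips <- NULL
  for (s in c("left", "right")) {
    f <- which(dom == "flexor" & side == s)
    e <- which(dom == "extensor" & side == s)
    if (length(f) && length(e)) { ips <- c(f[1], e[1]); break }
  }
  if (is.null(ips)) {
    stop("cannot form the ipsilateral flexor-extensor pair: need a flexor ",
         "and an extensor root on one side")
  }
  list(bilateral_flexor = bil, ipsilateral_flexor_extensor = ips)
}
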