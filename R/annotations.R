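#' Packaged Mbp 3' UTR localization annotations
#'
#' The published coordinates on the rat Mbp 3' UTR that anchor the
#' worked examples: the 127-nt localization signal (1-based 650-776) and
#' the reporter windows shown sufficient (520-770, 525-775) or
#' insufficient (400-650, 405-655) for projection localization. Stored
#' 1-based inclusive as published and converted to internal 0-based
#' half-open coordinates on load.
#'
#' @param role Optional filter: `"element"`, `"sufficient"` or
#'   `"insufficient"`.
#' @return Interval data.frame with an extra `role` column.
#' @examples
#' interval_length(mls_annotation("element"))  # 127
#' @export
mls_annotation <- function(role = NULL) {
  path <- system.file("extdata", "mls_annotation.tsv", package = "locsig",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(role)) {
    role <- match.arg(role, c("element", "sufficient", "insufficient"))
    tab <- tab[tab$role == role, , drop = FALSE]
  }
  iv <- from_onebased(tab$first, tab$last, ref_id = "Mbp_3utr",
                      name = tab$name)
  iv$role <- tab$role
  iv
}
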