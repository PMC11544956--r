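#' Parse 9-character sample label codes
#'
#' Sample measurements are labelled with a 9-character code: a sampling-site
#' letter (`E` eye, `G` gill, `M` muscle, `S` skin), `F` followed by a
#' two-digit fish number, the group letter (`C` control, `T` treated), a
#' two-digit exposure term (`03` = 3 h short-term, `24` = 24 h long-term),
#' and `_` followed by the replicate number. Example: `"EF03C03_1"` is
#' replicate 1 of the eye spectrum of control fish 3 at the short term.
#'
#' @param codes character vector of 9-character label codes.
#' @return A data.frame with one row per code and columns `site` (factor
#'   E/G/M/S), `fish` (integer), `group` (factor C/T), `term_hours`
#'   (integer, 3 or 24) and `replicate` (integer).
#' @seealso [formatSampleLabel()] for the exact inverse.
#' @examples
#' parseSampleLabel(c("EF03C03_1", "SF12T24_3"))
#' @export
parseSampleLabel <- function(codes) {
    codes <- as.character(codes)
    bad <- which(nchar(codes) != 9L)
    if (length(bad))
        stop("malformed label length (expected 9 characters): '",
             codes[bad[1L]], "'")
    site <- substr(codes, 1L, 1L)
    bad <- which(!site %in% c("E", "G", "M", "S"))
    if (length(bad))
        stop("unknown site '", site[bad[1L]], "' in label '",
             codes[bad[1L]], "'")
    if (any(substr(codes, 2L, 2L) != "F"))
        stop("malformed fish field (expected 'F' + two digits) in label '",
             codes[which(substr(codes, 2L, 2L) != "F")[1L]], "'")
    fishStr <- substr(codes, 3L, 4L)
    bad <- which(!grepl("^[0-9]{2}$", fishStr))
    if (length(bad))
        stop("malformed fish number '", fishStr[bad[1L]], "' in label '",
             codes[bad[1L]], "'")
    fish <- as.integer(fishStr)
    bad <- which(fish < 1L)
    if (length(bad))
        stop("fish number must be positive in label '", codes[bad[1L]], "'")
    group <- substr(codes, 5L, 5L)
    bad <- which(!group %in% c("C", "T"))
    if (length(bad))
        stop("unknown group '", group[bad[1L]], "' in label '",
             codes[bad[1L]], "'")
    termStr <- substr(codes, 6L, 7L)
    bad <- which(!termStr %in% c("03", "24"))
    if (length(bad))
        stop("term must be '03' or '24', got '", termStr[bad[1L]],
             "' in label '", codes[bad[1L]], "'")
    repField <- substr(codes, 8L, 9L)
    bad <- which(!grepl("^_[1-9]$", repField))
    if (length(bad))
        stop("malformed replicate field '", repField[bad[1L]],
             "' in label '", codes[bad[1L]], "'")
    data.frame(
        site = factor(site, levels = c("E", "G", "M", "S")),
        fish = fish,
        group = factor(group, levels = c("C", "T")),
        term_hours = as.integer(termStr),
        replicate = as.integer(substr(repField, 2L, 2L)),
        stringsAsFactors = FALSE
    )
}

#' Format sample label fields back into 9-character codes
#'
#' Exact inverse of [parseSampleLabel()] on the valid-code language.
#'
#' @param info data.frame with columns `site`, `fish`, `group`,
#'   `term_hours`, `replicate` (as returned by [parseSampleLabel()]), or
#'   the individual fields passed via `...` as equal-length vectors.
#' @param ... alternative to `info`: named fields `site`, `fish`, `group`,
#'   `term_hours`, `replicate`.
#' @return character vector of 9-character codes.
#' @examples
#' formatSampleLabel(site = "M", fish = 7, group = "T",
#'                   term_hours = 24, replicate = 2)
#' @export
formatSampleLabel <- function(info = NULL, ...) {
    if (is.null(info)) info <- data.frame(..., stringsAsFactors = FALSE)
    site <- as.character(info$site)
    group <- as.character(info$group)
    fish <- as.integer(info$fish)
    term <- as.integer(info$term_hours)
    repl <- as.integer(info$replicate)
    if (!all(site %in% c("E", "G", "M", "S")))
        stop("site must be one of E, G, M, S")
    if (!all(group %in% c("C", "T")))
        stop("group must be C or T")
    if (!all(term %in% c(3L, 24L)))
        stop("term_hours must be 3 or 24")
    if (any(fish < 1L | fish > 99L))
        stop("fish number must be in 1..99")
    if (any(repl < 1L | repl > 9L))
        stop("replicate must be in 1..9")
    sprintf("%sF%02d%s%02d_%d", site, fish, group, term, repl)
}
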