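#' Electrode montage: channel labels, ordering and scalp regions
#'
#' A montage fixes the canonical channel order used for all edge bookkeeping
#' and maps every channel to one of five scalp regions (frontal, central,
#' parietal, occipital, temporal). With `n` channels, the `n(n-1)/2`
#' unordered channel pairs ("edges") are enumerated row-wise over the upper
#' triangle: (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).
#'
#' @param labels character vector of unique channel names.
#' @param regions character vector, same length, each one of
#'   `"frontal"`, `"central"`, `"parietal"`, `"occipital"`, `"temporal"`.
#' @return An object of class `montage`: a data.frame with columns
#'   `label` and `region`, one row per channel in canonical order.
#' @seealso [default_montage()], [edge_pairs()], [edge_region_category()]
#' @export
montage <- function(labels, regions) {
  labels <- as.character(labels)
  regions <- as.character(regions)
  if (length(labels) != length(regions))
    stop("labels and regions must have equal length")
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  valid <- c("frontal", "central", "parietal", "occipital", "temporal")
  bad <- setdiff(unique(regions), valid)
  if (length(bad))
    stop("unknown region(s): ", paste(bad, collapse = ", "))
  out <- data.frame(label = labels, region = regions,
                    stringsAsFactors = FALSE)
  class(out) <- c("montage", "data.frame")
  out
}

#' The packaged 60-channel extended 10-20 montage
#'
#' Sixty scalp electrodes of a conventional 64-channel extended 10-20 cap
#' after discarding the two cerebellar leads and the two ocular channels
#' (CB1, CB2, HEO, VEO). The exact source cap is a conventional stand-in:
#' any 60-label montage can be substituted via [read_montage()].
#'
#' Regions follow a label-prefix rule: Fp/AF/F are frontal; FC/C central;
#' CP/P parietal; PO/O occipital; FT/T/TP temporal.
#'
#' @return A [montage] with 60 channels.
#' @examples
#' m <- default_montage()
#' nrow(m)                       # 60
#' nrow(edge_pairs(m))           # 1770 channel pairs
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage60.csv", package = "plinet",
                      mustWork = TRUE)
  read_montage(path)
}

#' Read a montage from a label,region CSV file
#'
#' @param path file with a `label,region` header line followed by one
#'   channel per line.
#' @return A [montage].
#' @export
read_montage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "region") %in% names(df)))
    stop("montage file must have columns 'label' and 'region': ", path)
  montage(df$label, df$region)
}

#' Scalp region of a channel
#'
#' @param mont a [montage].
#' @param label channel name(s).
#' @return character vector of regions.
#' @export
region_of <- function(mont, label) {
  idx <- match(label, mont$label)
  if (anyNA(idx))
    stop("unknown channel name(s): ",
         paste(label[is.na(idx)], collapse = ", "))
  mont$region[idx]
}

#' Enumerate all unordered channel pairs of a montage
#'
#' Pairs are listed row-wise over the upper triangle of the channel x
#' channel matrix: (1,2), (1,3), ..., (n-1,n). This order is the canonical
#' edge index used throughout the package.
#'
#' @param mont a [montage], or an integer channel count.
#' @return Integer matrix with columns `i`, `j` (i < j), one row per edge.
#' @export
edge_pairs <- function(mont) {
  n <- if (is.numeric(mont)) as.integer(mont) else nrow(mont)
  if (n < 2) stop("need at least 2 channels")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Edge index of a channel pair (and back)
#'
#' `edge_index(i, j, n)` returns the position of the unordered pair in the
#' canonical enumeration of [edge_pairs()]; `edge_from_index()` inverts it.
#'
#' @param i,j channel indices (order irrelevant, i != j).
#' @param n number of channels.
#' @param e edge index in 1..n(n-1)/2.
#' @return An integer edge index, or an integer vector `c(i, j)` with i < j.
#' @export
edge_index <- function(i, j, n) {
  if (any(i == j)) stop("no self edges")
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo < 1L) || any(hi > n)) stop("channel index out of range")
  as.integer((lo - 1L) * n - lo * (lo - 1L) / 2 + (hi - lo))
}

#' @rdname edge_index
#' @export
edge_from_index <- function(e, n) {
  npair <- n * (n - 1L) / 2
  if (any(e < 1L) || any(e > npair)) stop("edge index out of range")
  pairs <- edge_pairs(n)
  cbind(i = pairs[e, 1L], j = pairs[e, 2L])
}

#' Region category of an edge
#'
#' Canonical unordered region-pair label of a channel pair, e.g.
#' `"frontal-parietal"`. Frontal is listed first whenever present; otherwise
#' regions appear in the fixed order central, parietal, occipital, temporal.
#'
#' @param mont a [montage].
#' @param a,b channel names.
#' @return character scalar category label.
#' @examples
#' m <- default_montage()
#' edge_region_category(m, "Fp1", "F3")  # "frontal-frontal"
#' edge_region_category(m, "C3", "P3")   # "central-parietal"
#' @export
edge_region_category <- function(mont, a, b) {
  ra <- region_of(mont, a)
  rb <- region_of(mont, b)
  order_lvl <- c(frontal = 1L, central = 2L, parietal = 3L,
                 occipital = 4L, temporal = 5L)
  lo <- ifelse(order_lvl[ra] <= order_lvl[rb], ra, rb)
  hi <- ifelse(order_lvl[ra] <= order_lvl[rb], rb, ra)
  unname(paste0(lo, "-", hi))
}
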