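#' Ground-truth network from peer nominations
#'
#' Builds the reference ("ground-truth") friendship network from the six
#' sociometric nomination items. Each directed tie weight is the number of
#' distinct items on which `i` nominated `j`, divided by 6; the undirected
#' variant sums the nominations in both directions and divides by 12 (six
#' possible from each side). Weights therefore lie in `[0, 1]`, and an edge
#' exists wherever the weight is positive — nominations are never
#' thresholded.
#'
#' @param noms data frame of nomination records with columns `nominator`,
#'   `nominee`, `item` (1..6) and optionally `wave`. Repeated nominations of
#'   the same nominee on the same item count once.
#' @param roster character vector of node ids (or a data frame with an `id`
#'   column). Every nominator and nominee must be on the roster.
#' @param directed logical; build the directed (per-nominator) or the
#'   undirected (mutual) network.
#' @return a [social_network] with attribute `provenance = "nominations"`.
#' @examples
#' noms <- data.frame(nominator = "a", nominee = "b", item = 1:3,
#'                    wave = "W1")
#' gt_network(noms, roster = c("a", "b", "c"), directed = TRUE)
#' @export
gt_network <- function(noms, roster, directed = FALSE) {
  if (is.data.frame(roster)) roster <- roster$id
  roster <- as.character(roster)
  noms <- as.data.frame(noms)
  need <- c("nominator", "nominee", "item")
  if (!all(need %in% names(noms))) {
    stop("nominations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  noms$nominator <- as.character(noms$nominator)
  noms$nominee <- as.character(noms$nominee)
  noms$item <- as.integer(noms$item)
  if (nrow(noms) > 0 && any(noms$item < 1 | noms$item > 6)) {
    stop("nomination items must be in 1..6", call. = FALSE)
  }
  off <- setdiff(unique(c(noms$nominator, noms$nominee)), roster)
  if (length(off) > 0) {
    stop("node id(s) off roster: ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(noms) > 0 && any(noms$nominator == noms$nominee)) {
    stop("self-nominations are not allowed", call. = FALSE)
  }
  # item is binary per (nominator, nominee): count distinct items
  key <- paste(noms$nominator, noms$nominee, noms$item, sep = "\r")
  noms <- noms[!duplicated(key), , drop = FALSE]

  if (nrow(noms) == 0) {
    net <- social_network(nodes = roster, directed = directed)
  } else if (directed) {
    agg <- stats::aggregate(item ~ nominator + nominee, data = noms,
                            FUN = length)
    edges <- data.frame(from = agg$nominator, to = agg$nominee,
                        weight = agg$item / 6)
    net <- social_network(edges, nodes = roster, directed = TRUE)
  } else {
    a <- pmin(noms$nominator, noms$nominee)
    b <- pmax(noms$nominator, noms$nominee)
    agg <- stats::aggregate(list(n = noms$item),
                            by = list(from = a, to = b), FUN = length)
    edges <- data.frame(from = agg$from, to = agg$to, weight = agg$n / 12)
    net <- social_network(edges, nodes = roster, directed = FALSE)
  }
  attr(net, "provenance") <- "nominations"
  net
}
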