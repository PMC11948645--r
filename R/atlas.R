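#' Canonical network names
#'
#' The seven canonical resting-state networks used as the module partition
#' (Yeo-7 ordering: sensory through transmodal).
#' @export
YEO7_NETWORKS <- c("Visual", "Somatomotor", "DorsalAttention",
                   "VentralAttention", "Limbic", "Control", "DMN")

# approximate share of parcels per network in a 200-parcel cortical
# parcellation; used when no explicit sizes are given
.default_network_prop <- c(
  Visual = 0.155, Somatomotor = 0.165, DorsalAttention = 0.13,
  VentralAttention = 0.11, Limbic = 0.065, Control = 0.145, DMN = 0.23)

#' Build a parcel atlas with a 7-network partition
#'
#' Creates `P` parcels assigned to the seven canonical networks in
#' contiguous blocks. Default network sizes follow the approximate
#' proportions of a 200-parcel cortical parcellation; every network gets
#' at least one parcel.
#'
#' @param P number of parcels (at least 7; at least 14 guarantees two or
#'   more parcels per network under any allocation).
#' @param network_sizes optional integer vector of length 7 (ordered as
#'   [YEO7_NETWORKS]) summing to `P`.
#' @return object of class `parcel_atlas`: list with `parcel_id`
#'   (character) and `network_of` (factor over the 7 networks).
#' @examples
#' a <- make_atlas(14, network_sizes = rep(2, 7))
#' table(a$network_of)
#' @export
make_atlas <- function(P, network_sizes = NULL) {
  n_net <- length(YEO7_NETWORKS)
  if (!is.numeric(P) || length(P) != 1 || P < n_net)
    stop(sprintf("'P' must be at least %d (one parcel per network)", n_net),
         call. = FALSE)
  P <- as.integer(P)
  if (is.null(network_sizes)) {
    # one guaranteed parcel per network, remainder split by proportion
    base <- rep(1L, n_net)
    extra <- P - n_net
    raw <- .default_network_prop * extra
    sizes <- base + floor(raw)
    rem <- P - sum(sizes)
    if (rem > 0) {
      ord <- order(raw - floor(raw), decreasing = TRUE)
      sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
    }
  } else {
    if (length(network_sizes) != n_net)
      stop(sprintf("'network_sizes' must have length %d", n_net),
           call. = FALSE)
    sizes <- as.integer(network_sizes)
    if (any(sizes < 1) || sum(sizes) != P)
      stop("'network_sizes' must be positive and sum to P", call. = FALSE)
  }
  network <- factor(rep(YEO7_NETWORKS, times = sizes),
                    levels = YEO7_NETWORKS)
  structure(list(
    parcel_id = sprintf("parcel_%03d", seq_len(P)),
    network_of = network,
    P = P
  ), class = "parcel_atlas")
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat(sprintf("parcel_atlas: %d parcels over %d networks\n", x$P,
              nlevels(x$network_of)))
  print(table(x$network_of))
  invisible(x)
}

#' @export
as.data.frame.parcel_atlas <- function(x, ...) {
  data.frame(parcel_id = x$parcel_id, network = as.character(x$network_of),
             stringsAsFactors = FALSE)
}
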