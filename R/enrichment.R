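#' Exact upper-tail hypergeometric probability
#'
#' `p(X >= k)` for the overlap `k` between a property set of size `n` and a
#' focal set of size `K` drawn in a background of `N` proteins:
#' `sum_{x = k}^{min(n, K)} C(K, x) C(N - K, n - x) / C(N, n)`, evaluated via
#' the log-space stable distribution function.
#'
#' @param N Background size (total proteins assayed).
#' @param n Property-set size (e.g. differentially abundant proteins).
#' @param K Focal-set size (e.g. assayed network nodes).
#' @param k Observed overlap.
#' @return The upper-tail probability.
#' @export
#' @examples
#' hypergeom_upper(N = 10, n = 5, K = 4, k = 3)  # 66/252
hypergeom_upper <- function(N, n, K, k) {
  bad <- k < 0 || k > min(n, K) || n > N || K > N || n < 0 || K < 0
  if (is.na(bad) || bad) {
    abort("invalid hypergeometric parameters: need 0 <= k <= min(n, K), n <= N, K <= N",
          class = "ppirewire_input_error")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of one protein set within another
#'
#' Constructs the `(N, n, K, k)` contingency from set intersections against a
#' background universe and applies [hypergeom_upper()]. Elements of the
#' property or focal set absent from the background are trimmed with a
#' warning; duplicates and ordering are irrelevant.
#'
#' @param background Character vector: the assayed universe.
#' @param property_set Character vector: proteins with the property of
#'   interest (e.g. differentially abundant).
#' @param focal_set Character vector: the proteins whose enrichment is
#'   tested (e.g. rewired network nodes).
#' @return A one-row tibble: `N`, `n`, `K`, `k`, `p_value`.
#' @export
set_enrichment <- function(background, property_set, focal_set) {
  background <- unique(background)
  if (length(background) == 0) {
    abort("background must be non-empty", class = "ppirewire_input_error")
  }
  property_set <- unique(property_set)
  focal_set <- unique(focal_set)
  trim_p <- setdiff(property_set, background)
  trim_f <- setdiff(focal_set, background)
  if (length(trim_p) + length(trim_f) > 0) {
    warn(sprintf(
      "trimmed %d property and %d focal element(s) absent from the background",
      length(trim_p), length(trim_f)))
    property_set <- intersect(property_set, background)
    focal_set <- intersect(focal_set, background)
  }
  N <- length(background)
  n <- length(property_set)
  K <- length(focal_set)
  k <- length(intersect(property_set, focal_set))
  tibble(N = N, n = n, K = K, k = k,
         p_value = hypergeom_upper(N, n, K, k))
}

#' Protein-complex coverage in a network
#'
#' For every defined complex, the fraction of members present as network
#' nodes and the fraction of those present members that are rewired preys.
#' Complexes are flagged when presence is at least `presence_min` (inclusive)
#' and when the rewired fraction strictly exceeds `rewired_min`. The rewired
#' denominator is the members present in the network (the conservative
#' reading of "constituent proteins that are rewired"); set
#' `rewired_denominator = "all"` to use the full member list instead.
#'
#' @param complex_defs Named list of character vectors (complex -> members)
#'   or a tibble with columns `complex`, `member`.
#' @param net An `igraph` network.
#' @param rewired_preys Character vector of rewired prey identifiers.
#' @param presence_min Presence-fraction flag threshold (default 0.7,
#'   inclusive).
#' @param rewired_min Rewired-fraction flag threshold (default 0.6,
#'   exclusive).
#' @param rewired_denominator `"present"` (default) or `"all"`.
#' @return Tibble: `complex`, `n_members`, `n_present`, `presence_fraction`,
#'   `n_rewired`, `rewired_fraction`, `covered` flag, `rewired_flag`.
#' @export
complex_coverage <- function(complex_defs, net, rewired_preys = character(0),
                             presence_min = 0.7, rewired_min = 0.6,
                             rewired_denominator = c("present", "all")) {
  rewired_denominator <- match.arg(rewired_denominator)
  if (is.data.frame(complex_defs)) {
    complex_defs <- split(complex_defs$member, complex_defs$complex)
  }
  if (length(complex_defs) == 0) {
    abort("no complexes supplied", class = "ppirewire_input_error")
  }
  empty <- names(complex_defs)[lengths(complex_defs) == 0]
  if (length(empty) > 0) {
    warn(paste0("skipping complex(es) with empty member lists: ",
                paste(empty, collapse = ", ")))
    complex_defs <- complex_defs[lengths(complex_defs) > 0]
  }
  nodes <- igraph::V(net)$name
  purrr::imap_dfr(complex_defs, function(members, cx) {
    members <- unique(members)
    present <- intersect(members, nodes)
    rewired <- intersect(present, rewired_preys)
    denom <- if (rewired_denominator == "present") {
      length(present)
    } else {
      length(members)
    }
    tibble(
      complex = cx,
      n_members = length(members),
      n_present = length(present),
      presence_fraction = length(present) / length(members),
      n_rewired = length(rewired),
      rewired_fraction = if (denom == 0) 0 else length(rewired) / denom,
      covered = length(present) / length(members) >= presence_min,
      rewired_flag = (if (denom == 0) 0 else length(rewired) / denom) >
        rewired_min
    )
  })
}

#' Benjamini-Hochberg adjustment for batch enrichment runs
#'
#' Convenience wrapper adding a BH-adjusted q-value column to a tibble of
#' enrichment results (no correction is applied inside the individual tests).
#'
#' @param results Tibble with a `p_value` column.
#' @return `results` with a `q_value` column.
#' @export
adjust_enrichment <- function(results) {
  results |> mutate(q_value = p.adjust(.data$p_value, method = "BH"))
}
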