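#' Random connectivity by convergence numbers
#'
#' Each postsynaptic neuron receives exactly `n` distinct randomly picked
#' presynaptic partners (sampling without replacement, no self-connections).
#' Wiring is drawn independently per (pre, post) population pair from a seed
#' derived from the master seed and the pair's name, so the edge list is
#' bit-reproducible and invariant to the order in which pairs are listed.
#'
#' @param populations named integer vector of population sizes.
#' @param convergence tibble with columns `pre`, `post`, `n`.
#' @param seed master seed.
#' @return tibble with columns `pre_pop`, `post_pop`, `pre_id`, `post_id`
#'   (ids are 1-based within each population).
#' @export
build_connectivity <- function(populations, convergence, seed = 1L) {
  rows <- lapply(seq_len(nrow(convergence)), function(i) {
    pre <- convergence$pre[i]
    post <- convergence$post[i]
    n <- convergence$n[i]
    npre <- populations[[pre]]
    npost <- populations[[post]]
    pool <- if (pre == post) npre - 1L else npre
    if (n == 0L || npost == 0L) {
      return(tibble(pre_pop = character(), post_pop = character(),
                    pre_id = integer(), post_id = integer()))
    }
    if (n > pool) {
      abort(sprintf("convergence %d exceeds presynaptic pool %d for %s->%s",
                    n, pool, pre, post))
    }
    if (n == 0L) {
      return(tibble(pre_pop = character(), post_pop = character(),
                    pre_id = integer(), post_id = integer()))
    }
    withr::with_seed(derive_seed(seed, paste0("wiring_", pre, "_", post)), {
      pre_ids <- unlist(lapply(seq_len(npost), function(j) {
        cand <- if (pre == post) setdiff(seq_len(npre), j) else seq_len(npre)
        sample(cand, n)
      }))
    })
    tibble(pre_pop = pre, post_pop = post,
           pre_id = as.integer(pre_ids),
           post_id = rep(seq_len(npost), each = n))
  })
  dplyr::bind_rows(rows)
}
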