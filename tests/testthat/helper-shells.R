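# Generated shells are expensive; build each study shell once per test
# run and share it across test files.

.shell_cache <- new.env(parent = emptyenv())

study_shell_specs <- list(
  T9    = list(h = 3, k = 0),
  T9Q12 = list(h = 3, k = 0, h_prime = 4, k_prime = 0),
  T13   = list(h = 3, k = 1),
  T16   = list(h = 4, k = 0),
  T19   = list(h = 3, k = 2))

cached_shell <- function(name) {
  if (is.null(.shell_cache[[name]])) {
    sp <- study_shell_specs[[name]]
    sh <- generate_shell(sp$h, sp$k, sp$h_prime, sp$k_prime, seed = 1)
    .shell_cache[[name]] <- list(shell = sh, analysis = analyze_shell(sh))
  }
  .shell_cache[[name]]
}

# Canonical signature of an edge partition: the sorted set of sorted
# edge-key sets, with capsomere indices mapped onto manifest site ids
# by nearest centroid.  Two classifications agree iff signatures match.
partition_signature <- function(edges_i, edges_j, classes, site_of) {
  keys <- paste(pmin(site_of[edges_i], site_of[edges_j]),
                pmax(site_of[edges_i], site_of[edges_j]), sep = "-")
  sig <- vapply(split(keys, classes), function(k)
    paste(sort(k), collapse = "|"), "")
  sort(unname(sig))
}

map_caps_to_sites <- function(caps, manifest_sites) {
  ctr <- t(vapply(caps, `[[`, numeric(3), "centroid"))
  ms <- as.matrix(manifest_sites[, c("x", "y", "z")])
  d2 <- outer(rowSums(ctr^2), rowSums(ms^2), "+") - 2 * ctr %*% t(ms)
  site_of <- max.col(-d2)
  stopifnot(!anyDuplicated(site_of))
  site_of
}
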