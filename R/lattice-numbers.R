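#' Caspar-Klug triangulation number
#'
#' The triangulation number of an icosahedral lattice with indices
#' `(h, k)`, where `h` and `k` count the two-step connections linking
#' adjacent pentamers along the principal directions of the hexagonal
#' lattice: `T = h^2 + h*k + k^2`.
#'
#' @param h,k non-negative integer lattice indices; `h + k >= 1`.
#' @return the triangulation number, a positive integer.
#' @examples
#' triangulation_number(3, 0)  # 9
#' triangulation_number(3, 2)  # 19
#' @export
triangulation_number <- function(h, k) {
  h <- check_count(h, "h"); k <- check_count(k, "k")
  if (h + k < 1L) stop("degenerate lattice: h = k = 0", call. = FALSE)
  h * h + h * k + k * k
}

#' Elongation (Q) number of a prolate lattice
#'
#' The elongation number of a prolate (five-fold elongated) lattice with
#' body indices `(h', k')` counting the two-step connections linking
#' diagonal pentamers across the tubular midsection:
#' `Q = h*h' + h*k' + k*k'`.  A valid prolate body requires `Q >= T`;
#' `Q = T` degenerates to the icosahedral case.
#'
#' @inheritParams triangulation_number
#' @param h_prime,k_prime non-negative integer body indices.
#' @return the elongation number, a positive integer `>= T`.
#' @examples
#' elongation_number(3, 0, 4, 0)  # 12
#' @export
elongation_number <- function(h, k, h_prime, k_prime) {
  h <- check_count(h, "h"); k <- check_count(k, "k")
  hp <- check_count(h_prime, "h_prime"); kp <- check_count(k_prime, "k_prime")
  Tn <- triangulation_number(h, k)
  Q <- h * hp + h * kp + k * kp
  if (Q < Tn)
    stop(sprintf("Q = %d < T = %d describes an oblate/invalid body", Q, Tn),
         call. = FALSE)
  Q
}

#' Shell class (T and optional Q) from lattice indices
#'
#' Bundles the lattice indices with their derived triangulation and
#' elongation numbers.  A lattice is achiral when `k = 0` or `h = k`
#' (its mirror image is superimposable); otherwise it is chiral and the
#' `(h, k) -> (k, h)` swap gives the enantiomer.
#'
#' @inheritParams elongation_number
#' @param h_prime,k_prime optional body indices; both given makes the
#'   class prolate.
#' @return an object of class `"shell_class"`: a list with elements
#'   `h`, `k`, `h_prime`, `k_prime`, `T`, `Q`, `is_prolate`, `achiral`.
#' @examples
#' shell_class(3, 0)        # T = 9 icosahedral
#' shell_class(3, 0, 4, 0)  # T = 9, Q = 12 prolate
#' @export
shell_class <- function(h, k, h_prime = NULL, k_prime = NULL) {
  if (xor(is.null(h_prime), is.null(k_prime)))
    stop("give both h_prime and k_prime, or neither", call. = FALSE)
  Tn <- triangulation_number(h, k)
  prolate <- !is.null(h_prime)
  Q <- if (prolate) elongation_number(h, k, h_prime, k_prime) else NULL
  structure(list(h = as.integer(h), k = as.integer(k),
                 h_prime = if (prolate) as.integer(h_prime),
                 k_prime = if (prolate) as.integer(k_prime),
                 T = Tn, Q = Q,
                 is_prolate = prolate && Q > Tn,
                 achiral = (k == 0L || h == k)),
            class = "shell_class")
}

#' @export
print.shell_class <- function(x, ...) {
  cat(sprintf("Shell class: T = %d (h = %d, k = %d)%s, %s\n",
              x$T, x$h, x$k,
              if (!is.null(x$Q)) sprintf(", Q = %d (h' = %d, k' = %d)",
                                         x$Q, x$h_prime, x$k_prime) else "",
              if (x$achiral) "achiral" else "chiral"))
  invisible(x)
}

#' Predict capsomere stoichiometry of a closed shell
#'
#' Every closed shell carries exactly 12 pentamers.  An icosahedral
#' shell of triangulation number T carries `10(T - 1)` hexamers; a
#' prolate shell of elongation number Q carries `10(T - 1) + 5(Q - T)`.
#' When the number of scaffold-linker conformers per icosahedral
#' asymmetric unit is known, the number of linker copies is
#' `60 x conformers_per_au`.
#'
#' @param x a [shell_class()], or the triangulation number T directly.
#' @param Q optional elongation number when `x` is given as T.
#' @param conformers_per_au optional count of linker conformers per
#'   asymmetric unit.
#' @return a list with `n_pentamers` (always 12), `n_hexamers`, and
#'   (when requested) `n_linker_sites`.
#' @examples
#' predict_composition(shell_class(3, 0))        # 80 hexamers
#' predict_composition(shell_class(3, 0, 4, 0))  # 95 hexamers
#' predict_composition(19, conformers_per_au = 2)
#' @export
predict_composition <- function(x, Q = NULL, conformers_per_au = NULL) {
  if (inherits(x, "shell_class")) {
    Tn <- x$T; Q <- x$Q
  } else {
    Tn <- check_count(x, "T", min = 1L)
    if (!is.null(Q)) {
      Q <- check_count(Q, "Q", min = Tn)
    }
  }
  n_hex <- 10L * (Tn - 1L)
  if (!is.null(Q)) n_hex <- n_hex + 5L * (Q - Tn)
  out <- list(n_pentamers = 12L, n_hexamers = as.integer(n_hex))
  if (!is.null(conformers_per_au)) {
    out$n_linker_sites <- 60L * check_count(conformers_per_au,
                                            "conformers_per_au", min = 0L)
  }
  out
}
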