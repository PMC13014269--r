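#' Sample isotropic dye dipole orientations
#'
#' Draws `n` independent triples (donor transition dipole, acceptor transition
#' dipole, interdye separation direction), each uniform on the unit sphere.
#' Emulates rapid isotropic rotational averaging of the dye transition
#' dipoles; feeding the triples to [kappa_squared()] reproduces the isotropic
#' mean orientational factor of 2/3.
#'
#' @param n Number of triples.
#' @param seed Integer seed (NULL = current RNG stream).
#' @return A list of three n x 3 matrices: `donor`, `acceptor`, `separation`,
#'   each row a unit vector.
#' @examples
#' d <- sample_isotropic_dipoles(4, seed = 1)
#' rowSums(d$donor^2) # all 1
#' @export
sample_isotropic_dipoles <- function(n, seed = NULL) {
  stop_if(n < 1, "n must be at least 1")
  with_seed(seed, {
    one <- function() {
      m <- matrix(rnorm(3 * n), ncol = 3)
      m / sqrt(rowSums(m^2))
    }
    list(donor = one(), acceptor = one(), separation = one())
  })
}
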