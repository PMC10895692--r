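#' Enumerate the electronic basis states of the spin-free Hamiltonian
#'
#' Builds the ordered table of MCH (molecular Coulomb Hamiltonian) states for
#' a model with `n_singlets` singlet states and `n_triplets` triplet states.
#' Triplets carry their three spin sublevels (Sz = -1, 0, +1) as separate
#' basis states; singlets have Sz = 0. The ordering is the block convention
#' used by surface-hopping codes that treat intersystem crossing: singlets by
#' index first, then the triplets grouped by Sz block (-1, 0, +1) and by
#' index within each block, e.g. S0, S1, S2, S3, T1,-1, T2,-1, ..., T1,0,
#' T2,0, ..., T1,1, T2,1, ... This order is total and deterministic and is
#' the column order used for transition-count matrices.
#'
#' @param n_singlets number of singlet states (S0 upward)
#' @param n_triplets number of triplet states (T1 upward)
#' @return a data.frame with one row per basis state and columns
#'   `name` (e.g. "S0", "T1,-1"), `multiplicity` (1 or 3), `index`
#'   (0-based for singlets: S0 has index 0; 1-based for triplets: T1 has
#'   index 1), `sz` (-1, 0, or 1; 0 for singlets), and `collapsed`
#'   (the Sz-free label, e.g. "T1").
#' @export
#' @examples
#' spin_state_labels(4, 4)   # the 16 states S0..S3, T1..T4 x {-1,0,1}
spin_state_labels <- function(n_singlets, n_triplets) {
  stopifnot(n_singlets >= 1, n_triplets >= 0)
  s <- data.frame(
    multiplicity = 1L,
    index = seq_len(n_singlets) - 1L,
    sz = 0L
  )
  t <- expand.grid(index = seq_len(n_triplets), sz = c(-1L, 0L, 1L))
  t <- data.frame(multiplicity = 3L, index = t$index, sz = t$sz)
  out <- rbind(s, t)
  out$collapsed <- ifelse(out$multiplicity == 1L,
                          paste0("S", out$index),
                          paste0("T", out$index))
  out$name <- ifelse(out$multiplicity == 1L,
                     out$collapsed,
                     paste0(out$collapsed, ",", out$sz))
  rownames(out) <- NULL
  out[, c("name", "multiplicity", "index", "sz", "collapsed")]
}

#' Collapse an MCH state name to its Sz-free label
#'
#' Triplet sublevels ("T1,-1", "T1,0", "T1,1") are termed by their parent
#' triplet ("T1"); singlet names are unchanged. Product states and residence
#' totals are reported in this collapsed vocabulary.
#'
#' @param name character vector of MCH state names
#' @return character vector of collapsed labels
#' @export
collapse_label <- function(name) {
  sub(",.*$", "", name)
}
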