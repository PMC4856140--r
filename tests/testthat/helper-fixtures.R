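# Shared fixtures: a small tetragonal toy crystal keeps reflection counts
# low enough that brute-force oracles stay instant.

toy_cell <- function() tetragonal_cell(20, 30)
p41212 <- function() expand_ops("P41212")
p43212 <- function() expand_ops("P43212")
p1 <- function() expand_ops("P1")

toy_gt <- function(n_sites = 4, d_min = 2.5, f_double_prime = 0.7,
                   protein_scale = 200, seed = 3, ...) {
  build_ground_truth(toy_cell(), p41212(), n_sites = n_sites,
                     d_min = d_min, f_double_prime = f_double_prime,
                     protein_scale = protein_scale, seed = seed, ...)
}

# Exhaustive small index grid excluding (0,0,0)
hkl_grid <- function(hmax = 4) {
  H <- as.matrix(expand.grid(h = -hmax:hmax, k = -hmax:hmax,
                             l = -hmax:hmax))
  H[rowSums(abs(H)) > 0, , drop = FALSE]
}

random_sites <- function(n, seed) {
  set.seed(seed)
  data.frame(x = runif(n), y = runif(n), z = runif(n))
}
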