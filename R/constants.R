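# Shared constants and small helpers.

#' The 20 standard amino acids, one-letter codes, alphabetical
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter, including the common selenium substitutions
AA_321 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y",
  MSE = "M", SEC = "C"
)

# Kyte-Doolittle hydropathy
HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                W = -0.9, Y = -1.3)

# net formal charge at physiological pH (His partially protonated)
CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0,
            K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
            T = 0, V = 0, W = 0, Y = 0)

# Grantham polarity
POLARITY <- c(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0,
              H = 10.4, I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6,
              P = 8.0, Q = 10.5, R = 10.5, S = 9.2, T = 8.6, V = 5.9,
              W = 5.4, Y = 6.2)

# number of side-chain pseudo-atoms used by the synthetic structure
# generator, a coarse proxy for residue volume (glycine has none)
SIDECHAIN_ATOMS <- c(A = 1, C = 1, D = 2, E = 3, F = 4, G = 0, H = 3,
                     I = 2, K = 4, L = 2, M = 3, N = 2, P = 2, Q = 3,
                     R = 4, S = 1, T = 2, V = 2, W = 4, Y = 4)

#' Logistic (sigmoid) transform
#' @param x numeric vector
#' @return 1 / (1 + exp(-x))
#' @export
logistic <- function(x) 1 / (1 + exp(-x))

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package internals never perturb user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit hash of a string, used to derive per-structure seeds
string_seed <- function(id) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 2147480000
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
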