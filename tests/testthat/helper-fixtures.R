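# Small in-code fixtures shared across test files.

# a 12-subject sample sheet for one prandial state, 4 per BMI class,
# with all measured fatty acids and six leukocyte fractions
make_sheet <- function(state = "FS", n_per_class = 4L, seed = 42L) {
  set.seed(seed)
  n <- 3L * n_per_class
  subjects <- sprintf("S%02d", seq_len(n))
  bmi <- c(runif(n_per_class, 19, 24.5), runif(n_per_class, 25.1, 29.5),
           runif(n_per_class, 30.1, 39))
  fa_groups <- fa_saturation_groups()
  fa_names <- unlist(fa_groups, use.names = FALSE)
  fa <- matrix(runif(n * length(fa_names), 0.5, 25), n,
               dimnames = list(NULL, paste0("fa_", fa_names)))
  fa <- fa / rowSums(fa) * 100
  cells <- matrix(rgamma(n * 6, shape = 10), n)
  cells <- cells / rowSums(cells)
  colnames(cells) <- paste0("cell_", c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran"))
  df <- data.frame(sample_id = paste0(subjects, "_", state),
                   subject_id = subjects, prandial_state = state,
                   bmi = bmi, bmi_class = rep(c("N", "Ow", "Ob"), each = n_per_class),
                   age = runif(n, 25, 45), stringsAsFactors = FALSE)
  out <- cbind(df, as.data.frame(fa), as.data.frame(cells))
  class(out) <- c("sample_sheet", "data.frame")
  out
}

# dataset with given beta matrix rows and a matching sheet
make_dataset <- function(beta_rows, state = "FS", seed = 42L) {
  sheet <- make_sheet(state, seed = seed)
  beta <- do.call(rbind, beta_rows)
  rownames(beta) <- sprintf("cg%05d", seq_len(nrow(beta)))
  colnames(beta) <- sheet$sample_id
  methylation_dataset(beta, sheet)
}

expit2 <- function(m) 1 / (1 + 2^(-m))
logit2 <- function(b) log2(b / (1 - b))
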