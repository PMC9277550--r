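# Small in-code fixtures shared across test files.

toy_counts <- function() {
  abund_tbl(data.frame(
    stage = rep(c("A", "B", "C", "D"), each = 2),
    replicate = rep(1:2, 4),
    TaxA = c(10, 12, 20, 18, 40, 44, 80, 76),
    TaxB = c(40, 38, 30, 32, 20, 18, 5, 9),
    TaxC = c(50, 50, 50, 50, 40, 38, 15, 15)),
    kingdom = "fungal")
}

toy_volatiles <- function() {
  volatile_tbl(tidyr::expand_grid(
    stage = c("A", "B", "C", "D"),
    compound = c("EsterX", "AlcY")) |>
    dplyr::mutate(class = ifelse(compound == "EsterX", "ester", "alcohol"),
                  concentration = c(10, 100, 20, 80, 40, 60, 80, 20)))
}

# direct-sum Pearson correlation, the independent oracle for cor()
pearson_oracle <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
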