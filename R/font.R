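# Minimal 3x5 bitmap font for sheet header/footer text. Enough glyphs for
# the standard annotations ("ECG RECORD", paper speed and gain, lead names).
FONT3X5 <- list(
  "A" = c("010", "101", "111", "101", "101"),
  "C" = c("111", "100", "100", "100", "111"),
  "D" = c("110", "101", "101", "101", "110"),
  "E" = c("111", "100", "111", "100", "111"),
  "G" = c("111", "100", "101", "101", "111"),
  "I" = c("111", "010", "010", "010", "111"),
  "L" = c("100", "100", "100", "100", "111"),
  "M" = c("101", "111", "111", "101", "101"),
  "O" = c("111", "101", "101", "101", "111"),
  "P" = c("110", "101", "110", "100", "100"),
  "R" = c("110", "101", "110", "101", "101"),
  "S" = c("111", "100", "111", "001", "111"),
  "T" = c("111", "010", "010", "010", "010"),
  "V" = c("101", "101", "101", "101", "010"),
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "5" = c("111", "100", "111", "001", "111"),
  "/" = c("001", "001", "010", "100", "100"),
  " " = c("000", "000", "000", "000", "000")
)

# Rasterise `text` into a logical matrix (5*scale rows).
rasterText <- function(text, scale = 1L) {
  chars <- strsplit(toupper(text), "")[[1]]
  glyphs <- lapply(chars, function(ch) {
    g <- FONT3X5[[ch]]
    if (is.null(g)) g <- FONT3X5[[" "]]
    m <- do.call(rbind, lapply(g, function(r) as.integer(strsplit(r, "")[[1]]) > 0))
    cbind(m, FALSE)  # 1-px letter spacing
  })
  m <- do.call(cbind, glyphs)
  if (scale > 1L) m <- m[rep(seq_len(nrow(m)), each = scale),
                         rep(seq_len(ncol(m)), each = scale), drop = FALSE]
  m
}
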