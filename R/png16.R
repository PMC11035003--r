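# Minimal 16-bit grayscale PNG writer. The png package reads 16-bit files
# but only writes 8-bit, which is too coarse for ADC maps (8-bit quantizes
# a 0-2.5 x10^-3 mm^2/s range into ~0.01 steps). PNG structure: signature,
# IHDR, IDAT (zlib deflate of filter-byte-prefixed big-endian scanlines),
# IEND; each chunk carries a CRC-32.

# CRC-32 in two 16-bit halves so all values stay inside R's signed 32-bit
# integers. Polynomial 0xEDB88320.
crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    poly_hi <- 0xEDB8L; poly_lo <- 0x8320L
    hi <- integer(256); lo <- integer(256)
    for (i in 0:255) {
      ch <- 0L; cl <- i
      for (k in 1:8) {
        odd <- bitwAnd(cl, 1L) == 1L
        cl <- bitwOr(bitwShiftR(cl, 1L),
                     bitwShiftL(bitwAnd(ch, 1L), 15L))
        ch <- bitwShiftR(ch, 1L)
        if (odd) { ch <- bitwXor(ch, poly_hi); cl <- bitwXor(cl, poly_lo) }
      }
      hi[i + 1] <- ch; lo[i + 1] <- cl
    }
    tab <<- list(hi = hi, lo = lo)
    tab
  }
})

crc32 <- function(bytes) {
  tb <- crc32_table()
  ch <- 0xFFFFL; cl <- 0xFFFFL
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwAnd(bitwXor(cl, b), 0xFFL) + 1L
    cl <- bitwOr(bitwShiftR(cl, 8L),
                 bitwShiftL(bitwAnd(ch, 0xFFL), 8L))
    ch <- bitwShiftR(ch, 8L)
    ch <- bitwXor(ch, tb$hi[idx]); cl <- bitwXor(cl, tb$lo[idx])
  }
  ch <- bitwXor(ch, 0xFFFFL); cl <- bitwXor(cl, 0xFFFFL)
  c(bitwShiftR(ch, 8L), bitwAnd(ch, 0xFFL),
    bitwShiftR(cl, 8L), bitwAnd(cl, 0xFFL))
}

u32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, as.raw(crc32(body)))
}

# x: numeric matrix in [0, 1]; rows are image rows.
write_png16 <- function(x, path) {
  stopifnot(is.matrix(x), all(x >= 0 & x <= 1))
  h <- nrow(x); w <- ncol(x)
  v <- round(t(x) * 65535)      # scanlines are rows
  hi <- as.raw(v %/% 256); lo <- as.raw(v %% 256)
  scan <- matrix(raw(2 * w * h), nrow = 2 * w)
  scan[seq(1, 2 * w, 2), ] <- matrix(hi, nrow = w)
  scan[seq(2, 2 * w, 2), ] <- matrix(lo, nrow = w)
  idat <- memCompress(as.raw(rbind(raw(h), scan)), type = "gzip")
  ihdr <- c(u32be(w), u32be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit grayscale
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
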