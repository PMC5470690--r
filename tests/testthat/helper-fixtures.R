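# In-code fixtures: tiny rasters, CSVs and a deliberately unsupported
# 16-bit TIFF, all built at test time.

write_uniform_png <- function(path, h, w, rgb) {
  px <- array(rep(rgb / 255, each = h * w), dim = c(h, w, 3))
  png::writePNG(px, path)
  path
}

# planted label-map section without the generator: arbitrary colors per
# class, label codes supplied directly
section_from_codes <- function(codes, colors) {
  h <- nrow(codes); w <- ncol(codes)
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- matrix(colors[as.vector(codes), ch], h, w)
  mask <- matrix(codes != 5L, h, w)
  list(image = section_image(px), mask = roi_mask(mask),
       labels = qpia:::new_pixel_class_map(codes))
}

# valid baseline TIFF whose BitsPerSample values are patched to 16
write_16bit_tiff <- function(path) {
  qpia:::write_tiff_rgb(array(0L, dim = c(4, 4, 3)), path)
  raw <- readBin(path, "raw", n = file.size(path))
  n <- length(raw)
  raw[(n - 5):n] <- as.raw(c(16, 0, 16, 0, 16, 0))  # three little-endian SHORTs
  writeBin(raw, path)
  path
}

write_measurements_csv <- function(path, df) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

simple_measurements <- function() {
  expand <- expand.grid(replicate = 1:3, part = c("head", "body", "tail"),
                        day = 1:14, animal_id = c("a1", "a2", "a3"),
                        stringsAsFactors = FALSE)
  expand$emean_kpa <- 2 + 0.5 * expand$day + 0.01 * expand$replicate
  expand$sd_kpa <- 0.2
  expand[, c("animal_id", "day", "part", "replicate", "emean_kpa", "sd_kpa")]
}
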