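#include <Rcpp.h>
using namespace Rcpp;

// 2-bit genotype payload layout: code i occupies bits (2*(i%4))..(2*(i%4))+1
// of byte i/4, least-significant bits first; pad bits of the last byte are 0.
// Selection bit vectors use the same LSB-first convention (R packBits()).

// [[Rcpp::export]]
RawVector cpp_pack(IntegerVector codes) {
    R_xlen_t n = codes.size();
    R_xlen_t nb = (n + 3) / 4;
    RawVector out(nb);
    for (R_xlen_t i = 0; i < n; i++) {
        int c = codes[i];
        if (c == NA_INTEGER || c < 0 || c > 3)
            stop("genotype code at position %d is not in {0,1,2,3}", (int)(i + 1));
        out[i >> 2] |= (Rbyte)(c << ((i & 3) << 1));
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_unpack(RawVector payload, double n_snps) {
    R_xlen_t n = (R_xlen_t)n_snps;
    if ((R_xlen_t)payload.size() < (n + 3) / 4)
        stop("payload too short for %d genotypes", (int)n);
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; i++)
        out[i] = (payload[i >> 2] >> ((i & 3) << 1)) & 3;
    return out;
}

// positions are 0-based here; R-level wrappers are 1-based
// [[Rcpp::export]]
IntegerVector cpp_unpack_at(RawVector payload, IntegerVector pos0, double n_snps) {
    R_xlen_t n = (R_xlen_t)n_snps;
    R_xlen_t m = pos0.size();
    IntegerVector out(m);
    for (R_xlen_t k = 0; k < m; k++) {
        R_xlen_t i = pos0[k];
        if (i < 0 || i >= n)
            stop("position %d out of range [1, %d]", (int)(i + 1), (int)n);
        out[k] = (payload[i >> 2] >> ((i & 3) << 1)) & 3;
    }
    return out;
}

static inline bool bit_at(const Rbyte *bits, R_xlen_t i) {
    return (bits[i >> 3] >> (i & 7)) & 1;
}

// One scan over a list of packed records: per-SNP genotype-code counts
// (4 x n_snps, over all positions) and, per record, the number of no-calls
// (code 2) among the positions flagged active in `active_bits`.
// [[Rcpp::export]]
List cpp_scan_stats(List payloads, double n_snps, RawVector active_bits) {
    R_xlen_t n = (R_xlen_t)n_snps;
    R_xlen_t nrec = payloads.size();
    if ((R_xlen_t)active_bits.size() < (n + 7) / 8)
        stop("active bit vector too short");
    const Rbyte *act = RAW(active_bits);
    std::vector<int> counts(4 * (size_t)n, 0);
    IntegerVector nocall(nrec);
    for (R_xlen_t r = 0; r < nrec; r++) {
        RawVector pay = payloads[r];
        if ((R_xlen_t)pay.size() < (n + 3) / 4)
            stop("record %d payload too short", (int)(r + 1));
        const Rbyte *p = RAW(pay);
        int miss = 0;
        for (R_xlen_t i = 0; i < n; i++) {
            int c = (p[i >> 2] >> ((i & 3) << 1)) & 3;
            counts[(size_t)c * n + i]++;
            if (c == 2 && bit_at(act, i)) miss++;
        }
        nocall[r] = miss;
    }
    IntegerMatrix cm(4, (int)n);
    for (R_xlen_t i = 0; i < n; i++)
        for (int c = 0; c < 4; c++)
            cm(c, i) = counts[(size_t)c * n + i];
    return List::create(_["counts"] = cm, _["sample_nocall"] = nocall);
}

// One simulated sample on a panel: Hardy-Weinberg genotype at the given
// per-SNP minor allele frequency (allele2 is the minor allele), each call
// independently missing with probability nocall_rate. Uses the R RNG.
// [[Rcpp::export]]
RawVector cpp_sim_packed(NumericVector maf, double nocall_rate) {
    R_xlen_t n = maf.size();
    RawVector out((n + 3) / 4);
    for (R_xlen_t i = 0; i < n; i++) {
        double u = unif_rand();
        int c;
        if (u < nocall_rate) {
            c = 2;
        } else {
            double v = (u - nocall_rate) / (1.0 - nocall_rate);
            double q = maf[i], p = 1.0 - q;
            if (v < p * p) c = 0;
            else if (v < p * p + 2.0 * p * q) c = 1;
            else c = 3;
        }
        out[i >> 2] |= (Rbyte)(c << ((i & 3) << 1));
    }
    return out;
}
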