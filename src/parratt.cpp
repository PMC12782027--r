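#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Specular reflectivity of a slab stack by the Parratt recursion.
// Media are indexed 0 (fronting, semi-infinite) .. n+1 (backing,
// semi-infinite); sld/d describe the n finite slabs in between, ordered
// from the fronting side. No absorption: SLDs are real, the vertical
// wavevector k_j = sqrt((q/2)^2 - 4*pi*(sld_j - sld_fronting)) picks the
// principal complex branch, so evanescent waves decay below the critical
// edge and |r| = 1 there.
// [[Rcpp::export(name = ".parratt_cpp")]]
NumericVector parratt_cpp(NumericVector qz, NumericVector sld, NumericVector d,
                          double sld_fronting, double sld_backing) {
    const int nq = qz.size();
    const int n = sld.size();
    if (d.size() != n) stop("sld and d must have equal length");
    NumericVector out(nq);
    std::vector<std::complex<double> > k(n + 2);
    for (int iq = 0; iq < nq; ++iq) {
        const double q = qz[iq];
        const double k0sq = q * q / 4.0;
        k[0] = std::complex<double>(q / 2.0, 0.0);
        for (int j = 0; j < n; ++j)
            k[j + 1] = std::sqrt(std::complex<double>(
                k0sq - 4.0 * M_PI * (sld[j] - sld_fronting), 0.0));
        k[n + 1] = std::sqrt(std::complex<double>(
            k0sq - 4.0 * M_PI * (sld_backing - sld_fronting), 0.0));
        std::complex<double> r(0.0, 0.0);
        // recursion upward from the backing interface
        for (int j = n; j >= 0; --j) {
            std::complex<double> F = (k[j] - k[j + 1]) / (k[j] + k[j + 1]);
            if (j == n) {
                r = F;
            } else {
                // phase through slab j+1 (0-based index j in sld/d)
                std::complex<double> ph =
                    std::exp(std::complex<double>(0.0, 2.0) * k[j + 1] * d[j]);
                std::complex<double> rp = r * ph;
                r = (F + rp) / (1.0 + F * rp);
            }
        }
        out[iq] = std::norm(r);
    }
    return out;
}
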