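#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF (Frobenius loss), alternating one W and one C
// update per iteration from the supplied initialization. Returns the
// factors, the loss recorded after every iteration, and the iteration
// count. eps guards the denominators only.
// [[Rcpp::export(name = ".nmfMuCpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat C,
                      int max_iter, double tol, double eps) {
    std::vector<double> trace;
    trace.reserve(max_iter + 1);
    double loss = accu(square(V - W * C));
    trace.push_back(loss);
    bool converged = false;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
        W %= (V * C.t()) / (W * (C * C.t()) + eps);
        C %= (W.t() * V) / ((W.t() * W) * C + eps);
        double newloss = accu(square(V - W * C));
        trace.push_back(newloss);
        if (loss > 0 && (loss - newloss) / loss < tol) {
            loss = newloss;
            converged = true;
            break;
        }
        loss = newloss;
    }
    return Rcpp::List::create(
        Rcpp::Named("W") = W,
        Rcpp::Named("C") = C,
        Rcpp::Named("lossTrace") = trace,
        Rcpp::Named("iterations") = it + 1,
        Rcpp::Named("converged") = converged);
}
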