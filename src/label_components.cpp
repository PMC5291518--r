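#include <Rcpp.h>
#include <vector>

// Label maximal 8-connected components of TRUE pixels. Labels are assigned
// in column-major order of first encounter, so they are stable across runs.
// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components_8(Rcpp::LogicalMatrix mask) {
    const int H = mask.nrow(), W = mask.ncol();
    Rcpp::IntegerMatrix lab(H, W);
    std::vector<int> stack;
    int cur = 0;
    for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
            if (mask(i, j) == TRUE && lab(i, j) == 0) {
                ++cur;
                lab(i, j) = cur;
                stack.push_back(i + j * H);
                while (!stack.empty()) {
                    int p = stack.back();
                    stack.pop_back();
                    int pi = p % H, pj = p / H;
                    for (int dj = -1; dj <= 1; ++dj) {
                        for (int di = -1; di <= 1; ++di) {
                            int ni = pi + di, nj = pj + dj;
                            if (ni >= 0 && ni < H && nj >= 0 && nj < W &&
                                mask(ni, nj) == TRUE && lab(ni, nj) == 0) {
                                lab(ni, nj) = cur;
                                stack.push_back(ni + nj * H);
                            }
                        }
                    }
                }
            }
        }
    }
    return lab;
}
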