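#include <Rcpp.h>
#include <queue>
#include <vector>

// Random-priority flood fill: starting from `start` (1-based flat index of
// a dim[0] x dim[1] x dim[2] array), greedily absorb the frontier voxel
// with the smallest priority until `target` voxels are in the region.
// 6-connected by construction; irregular boundaries come from the i.i.d.
// priorities. Returns the 1-based flat indices of the region.
// [[Rcpp::export]]
Rcpp::IntegerVector grow_region_cpp(Rcpp::IntegerVector dim,
                                    int start,
                                    int target,
                                    Rcpp::NumericVector priority) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (priority.size() != nvox)
    Rcpp::stop("priority vector length must equal the voxel count");
  if (start < 1 || start > nvox)
    Rcpp::stop("start voxel outside the grid");
  if (target < 1 || target > nvox)
    Rcpp::stop("target voxel count outside the grid capacity");

  std::vector<char> seen(nvox, 0);
  typedef std::pair<double, int> Node; // (priority, 0-based flat index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;
  std::vector<int> region;
  region.reserve(target);

  int s0 = start - 1;
  heap.push(Node(priority[s0], s0));
  seen[s0] = 1;

  while (!heap.empty() && (int)region.size() < target) {
    int v = heap.top().second;
    heap.pop();
    region.push_back(v);
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int w = xx + nx * (yy + ny * zz);
      if (!seen[w]) {
        seen[w] = 1;
        heap.push(Node(priority[w], w));
      }
    }
  }
  if ((int)region.size() < target)
    Rcpp::stop("region growth exhausted the grid before reaching target");
  Rcpp::IntegerVector out(region.size());
  for (size_t i = 0; i < region.size(); ++i) out[i] = region[i] + 1;
  return out;
}
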