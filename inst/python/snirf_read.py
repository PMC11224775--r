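#!/usr/bin/env python
"""Dump the probe group and measurement list of a SNIRF file to JSON.

Usage: snirf_read.py in.snirf out.json
"""
import json
import sys

import h5py


def to_str(value):
    return value.decode() if isinstance(value, bytes) else str(value)


def main(snirf_path, json_path):
    out = {}
    with h5py.File(snirf_path, "r") as f:
        out["formatVersion"] = to_str(f["formatVersion"][()])
        nirs = f["nirs1"] if "nirs1" in f else f["nirs"]
        out["metaDataTags"] = {
            key: to_str(nirs["metaDataTags"][key][()])
            for key in nirs["metaDataTags"]}
        probe = {}
        pg = nirs["probe"]
        for key in pg:
            value = pg[key][()]
            if key in ("sourceLabels", "detectorLabels"):
                probe[key] = [to_str(v) for v in value]
            else:
                probe[key] = value.tolist()
        out["probe"] = probe
        ml = {"sourceIndex": [], "detectorIndex": [], "wavelengthIndex": []}
        data = nirs["data1"]
        k = 1
        while "measurementList%d" % k in data:
            entry = data["measurementList%d" % k]
            for key in ml:
                ml[key].append(int(entry[key][()]))
            k += 1
        out["measurementList"] = ml
    with open(json_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.exit(__doc__)
    main(sys.argv[1], sys.argv[2])
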