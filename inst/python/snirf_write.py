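#!/usr/bin/env python
"""Write a probe-only SNIRF (HDF5) file from a JSON intermediate.

Usage: snirf_write.py probe.json out.snirf

The JSON carries formatVersion, metaDataTags, probe (wavelengths,
sourcePos3D, detectorPos3D, optional 2D positions, labels) and a
measurementList table. A zero placeholder data block is written so the file
carries the required data1 group (no optical time series is simulated).
"""
import json
import sys

import h5py
import numpy as np


def write_string(group, name, value):
    group.create_dataset(name, data=np.bytes_(str(value)))


def main(json_path, snirf_path):
    with open(json_path) as fh:
        st = json.load(fh)
    probe = st["probe"]
    ml = st["measurementList"]
    n_meas = len(ml["sourceIndex"])
    with h5py.File(snirf_path, "w") as f:
        write_string(f, "formatVersion", st.get("formatVersion", "1.1"))
        nirs = f.create_group("nirs1")
        meta = nirs.create_group("metaDataTags")
        for tag, value in st.get("metaDataTags", {}).items():
            write_string(meta, tag, value)
        pg = nirs.create_group("probe")
        pg.create_dataset("wavelengths",
                          data=np.asarray(probe["wavelengths"], dtype=float))
        for key in ("sourcePos3D", "detectorPos3D",
                    "sourcePos2D", "detectorPos2D"):
            if probe.get(key) is not None:
                pg.create_dataset(key,
                                  data=np.asarray(probe[key], dtype=float))
        for key in ("sourceLabels", "detectorLabels"):
            if probe.get(key) is not None:
                pg.create_dataset(
                    key, data=np.array(probe[key], dtype=h5py.string_dtype()))
        data = nirs.create_group("data1")
        data.create_dataset("dataTimeSeries",
                            data=np.zeros((1, n_meas), dtype=float))
        data.create_dataset("time", data=np.asarray([0.0]))
        for k in range(n_meas):
            entry = data.create_group("measurementList%d" % (k + 1))
            entry.create_dataset("sourceIndex",
                                 data=np.int32(ml["sourceIndex"][k]))
            entry.create_dataset("detectorIndex",
                                 data=np.int32(ml["detectorIndex"][k]))
            entry.create_dataset("wavelengthIndex",
                                 data=np.int32(ml["wavelengthIndex"][k]))
            entry.create_dataset("dataType", data=np.int32(1))
            entry.create_dataset("dataTypeIndex", data=np.int32(1))


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.exit(__doc__)
    main(sys.argv[1], sys.argv[2])
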