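# Generates a small synthetic DICOM series with pydicom (independent of the
# package's own DICOM parser), used to validate the series reader.
write_dicom_series_fixture <- function(dir, n_slices = 10L, rows = 12L,
                                       cols = 16L, pixel_spacing = c(0.3, 0.35),
                                       slice_spacing = 0.5,
                                       origin = c(1, 2, 3)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  script <- sprintf('
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
import numpy as np, os

out = %s
n, rows, cols = %d, %d, %d
ps = [%f, %f]          # (row spacing, col spacing)
dz = %f
origin = [%f, %f, %f]
series = generate_uid()
rng = np.random.default_rng(0)
for k in range(n):
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = Dataset()
    ds.file_meta = meta
    ds.SOPClassUID = meta.MediaStorageSOPClassUID
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.SeriesInstanceUID = series
    ds.Modality = "CT"
    ds.Rows, ds.Columns = rows, cols
    ds.PixelSpacing = [str(ps[0]), str(ps[1])]
    ds.ImageOrientationPatient = ["1", "0", "0", "0", "1", "0"]
    ds.ImagePositionPatient = [str(origin[0]), str(origin[1]), str(origin[2] + k * dz)]
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleIntercept = "-1000"
    ds.RescaleSlope = "1"
    arr = (k * 1000 + np.arange(rows * cols).reshape(rows, cols)).astype(np.int16)
    ds.PixelData = arr.tobytes()
    ds.is_little_endian = True
    ds.is_implicit_VR = False
    pydicom.dcmwrite(os.path.join(out, "slice_%%03d.dcm" %% k), ds,
                     enforce_file_format=True)
print("ok")
', deparse(dir), n_slices, rows, cols, pixel_spacing[1], pixel_spacing[2],
    slice_spacing, origin[1], origin[2], origin[3])
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- suppressWarnings(system2("python", sf, stdout = TRUE, stderr = TRUE))
  if (!any(grepl("^ok$", out)))
    stop("pydicom fixture generation failed: ", paste(out, collapse = "\n"))
  invisible(dir)
}
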