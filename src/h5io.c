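/* Minimal HDF5 container IO for raw-data round trips.
 *
 * Supports double / integer / complex arrays and scalar strings. Complex
 * data use a compound type with double fields "r" and "i" (the convention
 * h5py uses), which matches the memory layout of R's Rcomplex. Array
 * dimensions are stored in C (row-major) order, i.e. reversed relative to
 * the R dim attribute; the R wrappers restore them on read. Object time
 * tracking is disabled so identical inputs give byte-identical files.
 */

#include <stdlib.h>
#include <string.h>
#include <hdf5.h>
#include <R.h>
#include <Rinternals.h>

static hid_t complex_type(void)
{
    hid_t t = H5Tcreate(H5T_COMPOUND, 2 * sizeof(double));
    H5Tinsert(t, "r", 0, H5T_NATIVE_DOUBLE);
    H5Tinsert(t, "i", sizeof(double), H5T_NATIVE_DOUBLE);
    return t;
}

/* Create intermediate groups for a path like /meta/grid_shape. */
static void ensure_groups(hid_t file, const char *name)
{
    char buf[1024];
    size_t n = strlen(name);
    if (n >= sizeof(buf)) error("dataset name too long");
    strcpy(buf, name);
    for (size_t i = 1; i < n; i++) {
        if (buf[i] != '/') continue;
        buf[i] = '\0';
        if (H5Lexists(file, buf, H5P_DEFAULT) <= 0) {
            hid_t gcpl = H5Pcreate(H5P_GROUP_CREATE);
            H5Pset_obj_track_times(gcpl, 0);
            hid_t g = H5Gcreate2(file, buf, H5P_DEFAULT, gcpl, H5P_DEFAULT);
            if (g < 0) error("failed to create HDF5 group '%s'", buf);
            H5Gclose(g);
            H5Pclose(gcpl);
        }
        buf[i] = '/';
    }
}

static void write_one(hid_t file, const char *name, SEXP obj)
{
    ensure_groups(file, name);

    hid_t dcpl = H5Pcreate(H5P_DATASET_CREATE);
    H5Pset_obj_track_times(dcpl, 0);

    SEXP dimattr = Rf_getAttrib(obj, R_DimSymbol);
    int rank;
    hsize_t dims[8];
    if (dimattr != R_NilValue) {
        rank = Rf_length(dimattr);
        if (rank > 8) error("arrays of rank > 8 are not supported");
        for (int i = 0; i < rank; i++)  /* reverse: C order in the file */
            dims[i] = (hsize_t) INTEGER(dimattr)[rank - 1 - i];
    } else {
        rank = 1;
        dims[0] = (hsize_t) Rf_xlength(obj);
    }

    hid_t space, dset, mtype = -1, ftype = -1;
    if (TYPEOF(obj) == STRSXP && Rf_xlength(obj) == 1) {
        const char *s = CHAR(STRING_ELT(obj, 0));
        ftype = H5Tcopy(H5T_C_S1);
        H5Tset_size(ftype, strlen(s) + 1);
        space = H5Screate(H5S_SCALAR);
        dset = H5Dcreate2(file, name, ftype, space, H5P_DEFAULT, dcpl,
                          H5P_DEFAULT);
        if (dset < 0) error("failed to create HDF5 dataset '%s'", name);
        H5Dwrite(dset, ftype, H5S_ALL, H5S_ALL, H5P_DEFAULT, s);
    } else {
        space = H5Screate_simple(rank, dims, NULL);
        switch (TYPEOF(obj)) {
        case REALSXP:
            mtype = H5Tcopy(H5T_NATIVE_DOUBLE);
            ftype = H5Tcopy(H5T_NATIVE_DOUBLE);
            break;
        case INTSXP:
            mtype = H5Tcopy(H5T_NATIVE_INT);
            ftype = H5Tcopy(H5T_NATIVE_INT);
            break;
        case CPLXSXP:
            mtype = complex_type();
            ftype = complex_type();
            break;
        default:
            error("unsupported R type for HDF5 dataset '%s'", name);
        }
        dset = H5Dcreate2(file, name, ftype, space, H5P_DEFAULT, dcpl,
                          H5P_DEFAULT);
        if (dset < 0) error("failed to create HDF5 dataset '%s'", name);
        const void *buf =
            TYPEOF(obj) == REALSXP ? (const void *) REAL(obj) :
            TYPEOF(obj) == INTSXP  ? (const void *) INTEGER(obj) :
                                     (const void *) COMPLEX(obj);
        if (H5Dwrite(dset, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0)
            error("failed to write HDF5 dataset '%s'", name);
        if (mtype >= 0) H5Tclose(mtype);
    }
    if (ftype >= 0) H5Tclose(ftype);
    H5Sclose(space);
    H5Dclose(dset);
    H5Pclose(dcpl);
}

SEXP C_h5_write(SEXP path, SEXP names, SEXP objects)
{
    hid_t fcpl = H5Pcreate(H5P_FILE_CREATE);
    H5Pset_obj_track_times(fcpl, 0);
    hid_t file = H5Fcreate(CHAR(STRING_ELT(path, 0)), H5F_ACC_TRUNC,
                           fcpl, H5P_DEFAULT);
    H5Pclose(fcpl);
    if (file < 0)
        error("cannot create HDF5 file '%s'", CHAR(STRING_ELT(path, 0)));
    for (R_xlen_t i = 0; i < Rf_xlength(names); i++)
        write_one(file, CHAR(STRING_ELT(names, i)), VECTOR_ELT(objects, i));
    H5Fclose(file);
    return R_NilValue;
}

SEXP C_h5_exists(SEXP path, SEXP name)
{
    hid_t file = H5Fopen(CHAR(STRING_ELT(path, 0)), H5F_ACC_RDONLY,
                         H5P_DEFAULT);
    if (file < 0)
        error("cannot open HDF5 file '%s'", CHAR(STRING_ELT(path, 0)));
    /* check every component of the path */
    char buf[1024];
    const char *nm = CHAR(STRING_ELT(name, 0));
    if (strlen(nm) >= sizeof(buf)) error("dataset name too long");
    strcpy(buf, nm);
    int ok = 1;
    for (size_t i = 1; i <= strlen(nm); i++) {
        if (nm[i] != '/' && nm[i] != '\0') continue;
        buf[i] = '\0';
        if (H5Lexists(file, buf, H5P_DEFAULT) <= 0) { ok = 0; break; }
        buf[i] = nm[i];
    }
    H5Fclose(file);
    return Rf_ScalarLogical(ok);
}

SEXP C_h5_read(SEXP path, SEXP name)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    const char *dname = CHAR(STRING_ELT(name, 0));
    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s'", fname);
    if (H5Lexists(file, dname, H5P_DEFAULT) <= 0) {
        H5Fclose(file);
        error("HDF5 file '%s' is missing dataset '%s'", fname, dname);
    }
    hid_t dset = H5Dopen2(file, dname, H5P_DEFAULT);
    if (dset < 0) {
        H5Fclose(file);
        error("cannot open HDF5 dataset '%s'", dname);
    }
    hid_t space = H5Dget_space(dset);
    hid_t ftype = H5Dget_type(dset);
    H5T_class_t cls = H5Tget_class(ftype);
    int rank = H5Sget_simple_extent_ndims(space);
    hsize_t dims[8];
    if (rank > 8) error("arrays of rank > 8 are not supported");
    H5Sget_simple_extent_dims(space, dims, NULL);
    R_xlen_t n = 1;
    for (int i = 0; i < rank; i++) n *= (R_xlen_t) dims[i];

    SEXP out;
    if (cls == H5T_COMPOUND) {
        out = PROTECT(Rf_allocVector(CPLXSXP, n));
        hid_t mtype = complex_type();
        if (H5Dread(dset, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    COMPLEX(out)) < 0)
            error("failed to read HDF5 dataset '%s'", dname);
        H5Tclose(mtype);
    } else if (cls == H5T_INTEGER) {
        out = PROTECT(Rf_allocVector(INTSXP, n));
        if (H5Dread(dset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    INTEGER(out)) < 0)
            error("failed to read HDF5 dataset '%s'", dname);
    } else if (cls == H5T_FLOAT) {
        out = PROTECT(Rf_allocVector(REALSXP, n));
        if (H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    REAL(out)) < 0)
            error("failed to read HDF5 dataset '%s'", dname);
    } else if (cls == H5T_STRING) {
        size_t len = H5Tget_size(ftype);
        char *buf = (char *) R_alloc(len + 1, 1);
        hid_t mtype = H5Tcopy(H5T_C_S1);
        H5Tset_size(mtype, len + 1);
        if (H5Dread(dset, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0)
            error("failed to read HDF5 dataset '%s'", dname);
        buf[len] = '\0';
        H5Tclose(mtype);
        out = PROTECT(Rf_mkString(buf));
    } else {
        error("unsupported HDF5 datatype in dataset '%s'", dname);
        out = R_NilValue; /* unreached */
    }
    if (rank > 1) {
        SEXP dim = PROTECT(Rf_allocVector(INTSXP, rank));
        for (int i = 0; i < rank; i++)   /* restore R (column-major) order */
            INTEGER(dim)[i] = (int) dims[rank - 1 - i];
        Rf_setAttrib(out, R_DimSymbol, dim);
        UNPROTECT(1);
    }
    H5Tclose(ftype);
    H5Sclose(space);
    H5Dclose(dset);
    H5Fclose(file);
    UNPROTECT(1);
    return out;
}
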