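"patient","art_sd"
"P00001","2007-04-13"
"P00002","2008-07-19"
"P00003","2011-02-16"
"P00004","2010-12-19"
"P00005","2009-07-27"
"P00006","2004-10-24"
"P00007","2010-12-29"
"P00008","2002-12-16"
"P00009","2007-09-25"
"P00010","2007-11-28"
"P00011","2010-12-16"
"P00012","2010-02-24"
"P00013","2010-02-04"
"P00014","2002-03-25"
"P00015","2004-05-25"
"P00016","2007-11-26"
"P00017","2003-10-09"
"P00018","2007-08-22"
"P00019","2010-02-21"
"P00020","2009-09-03"
"P00021","2007-03-13"
"P00022","2006-01-20"
"P00023","2004-05-20"
"P00024","2011-07-11"
"P00025","2002-11-29"
"P00026","2003-01-08"
"P00027","2007-01-02"
"P00028","2010-12-06"
"P00029","2011-04-16"
"P00030","2006-09-23"
"P00031","2003-12-15"
"P00032","2006-04-19"
"P00033","2007-07-01"
"P00034","2003-07-17"
"P00035","2010-06-02"
"P00036","2006-01-28"
"P00037","2009-05-06"
"P00038","2004-12-25"
"P00039","2005-03-30"
"P00040","2003-09-30"
"P00041","2004-09-28"
"P00042","2005-06-01"
"P00043","2005-03-31"
"P00044","2005-10-27"
"P00045","2011-06-09"
"P00046","2008-03-20"
"P00047","2003-04-27"
"P00048","2011-12-09"
"P00049","2008-07-22"
"P00050","2008-03-24"
"P00051","2007-07-21"
"P00052","2011-09-01"
"P00053","2004-01-29"
"P00054","2006-02-26"
"P00055","2008-10-28"
"P00056","2010-05-07"
"P00057","2009-05-03"
"P00058","2007-11-24"
"P00059","2011-01-13"
"P00060","2002-01-23"
"P00061","2005-12-15"
"P00062","2003-02-13"
"P00063","2006-05-11"
"P00064","2008-09-09"
"P00065","2003-11-07"
"P00066","2012-01-11"
"P00067","2003-01-23"
"P00068","2011-03-23"
"P00069","2007-04-27"
"P00070","2011-04-30"
"P00071","2006-08-18"
"P00072","2008-04-21"
"P00073","2003-09-11"
"P00074","2003-10-18"
"P00075","2006-04-11"
"P00076","2008-04-24"
"P00077","2009-12-28"
"P00078","2009-11-18"
"P00079","2011-08-04"
"P00080","2005-03-27"
"P00081","2004-09-05"
"P00082","2011-09-10"
"P00083","2003-01-11"
"P00084","2005-02-12"
"P00085","2006-11-28"
"P00086","2002-09-24"
"P00087","2008-05-18"
"P00088","2011-03-30"
"P00089","2009-05-23"
"P00090","2003-06-23"
"P00091","2010-01-23"
"P00092","2002-10-23"
"P00093","2004-11-05"
"P00094","2009-04-17"
"P00095","2011-01-30"
"P00096","2009-05-03"
"P00097","2005-08-10"
"P00098","2003-10-14"
"P00099","2010-04-15"
"P00100","2008-04-13"
"P00101","2006-11-04"
"P00102","2010-09-21"
"P00103","2002-11-17"
"P00104","2003-06-27"
"P00105","2003-04-12"
"P00106","2006-04-27"
"P00107","2010-04-15"
"P00108","2005-09-12"
"P00109","2007-01-30"
"P00110","2008-12-22"
"P00111","2011-12-01"
"P00112","2006-07-10"
"P00113","2004-11-28"
"P00114","2008-12-29"
"P00115","2004-04-13"
"P00116","2004-10-11"
"P00117","2003-09-11"
"P00118","2010-06-30"
"P00119","2003-10-09"
"P00120","2010-02-21"
"P00121","2008-05-11"
"P00122","2005-10-23"
"P00123","2003-10-02"
"P00124","2005-01-02"
"P00125","2005-03-21"
"P00126","2011-04-02"
"P00127","2009-09-26"
"P00128","2003-04-18"
"P00129","2007-05-17"
"P00130","2008-08-13"
"P00131","2004-07-21"
"P00132","2010-12-16"
"P00133","2009-03-05"
"P00134","2003-09-04"
"P00135","2002-05-14"
"P00136","2007-08-21"
"P00137","2002-06-09"
"P00138","2004-05-03"
"P00139","2002-03-11"
"P00140","2009-11-29"
"P00141","2002-08-19"
"P00142","2008-04-02"
"P00143","2007-12-27"
"P00144","2010-10-22"
"P00145","2007-04-17"
"P00146","2006-02-12"
"P00147","2009-01-07"
"P00148","2007-04-21"
"P00149","2010-08-06"
"P00150","2011-05-08"
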