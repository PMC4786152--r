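"patient","death_y","l_alive_d"
"P00001",0,"2010-04-17"
"P00002",0,"2011-07-24"
"P00003",0,"2014-02-20"
"P00004",1,"2011-06-06"
"P00005",1,"2009-10-03"
"P00006",0,"2006-10-29"
"P00007",0,"2014-01-02"
"P00008",1,"2005-09-26"
"P00009",1,"2008-01-30"
"P00010",0,"2010-03-29"
"P00011",1,"2012-10-31"
"P00012",0,"2013-02-28"
"P00013",0,"2013-02-08"
"P00014",1,"2002-12-17"
"P00015",0,"2004-11-14"
"P00016",0,"2010-11-30"
"P00017",0,"2006-10-13"
"P00018",0,"2010-08-26"
"P00019",0,"2013-02-25"
"P00020",0,"2010-05-30"
"P00021",0,"2010-03-17"
"P00022",0,"2009-01-24"
"P00023",0,"2007-05-25"
"P00024",0,"2014-07-15"
"P00025",0,"2005-12-03"
"P00026",1,"2004-02-09"
"P00027",0,"2010-01-06"
"P00028",0,"2013-12-10"
"P00029",1,"2011-05-06"
"P00030",0,"2009-09-27"
"P00031",0,"2006-12-19"
"P00032",0,"2009-04-23"
"P00033",0,"2010-07-05"
"P00034",1,"2004-11-07"
"P00035",0,"2013-06-06"
"P00036",0,"2009-02-01"
"P00037",1,"2011-02-19"
"P00038",0,"2007-12-30"
"P00039",0,"2008-04-03"
"P00040",0,"2006-10-04"
"P00041",0,"2007-10-03"
"P00042",0,"2008-06-05"
"P00043",1,"2006-06-19"
"P00044",0,"2008-10-31"
"P00045",0,"2014-06-13"
"P00046",0,"2011-03-25"
"P00047",1,"2004-09-30"
"P00048",1,"2013-06-25"
"P00049",0,"2011-07-27"
"P00050",1,"2009-06-22"
"P00051",0,"2010-07-25"
"P00052",0,"2014-09-05"
"P00053",0,"2007-02-02"
"P00054",0,"2009-03-02"
"P00055",0,"2011-11-02"
"P00056",0,"2013-05-11"
"P00057",1,"2012-02-17"
"P00058",0,"2010-11-28"
"P00059",0,"2014-01-17"
"P00060",0,"2005-01-27"
"P00061",0,"2008-12-19"
"P00062",0,"2006-02-17"
"P00063",1,"2006-07-02"
"P00064",1,"2010-10-01"
"P00065",0,"2006-11-11"
"P00066",1,"2013-11-28"
"P00067",0,"2006-01-27"
"P00068",0,"2014-03-27"
"P00069",0,"2010-05-01"
"P00070",0,"2014-05-04"
"P00071",0,"2009-08-22"
"P00072",0,"2011-04-26"
"P00073",1,"2006-07-17"
"P00074",1,"2005-12-02"
"P00075",0,"2009-04-15"
"P00076",0,"2011-04-29"
"P00077",1,"2010-01-13"
"P00078",0,"2012-11-22"
"P00079",1,"2012-11-02"
"P00080",0,"2008-03-31"
"P00081",1,"2004-12-02"
"P00082",0,"2013-10-21"
"P00083",0,"2006-01-15"
"P00084",0,"2008-02-17"
"P00085",0,"2009-12-02"
"P00086",1,"2003-12-31"
"P00087",0,"2011-05-23"
"P00088",1,"2011-05-26"
"P00089",0,"2012-05-27"
"P00090",0,"2006-06-27"
"P00091",1,"2010-04-14"
"P00092",0,"2005-10-27"
"P00093",0,"2007-11-10"
"P00094",0,"2012-04-21"
"P00095",1,"2012-08-14"
"P00096",1,"2009-06-10"
"P00097",0,"2008-08-14"
"P00098",1,"2005-09-29"
"P00099",0,"2013-04-19"
"P00100",1,"2010-04-27"
"P00101",0,"2009-11-08"
"P00102",0,"2013-09-25"
"P00103",0,"2005-11-21"
"P00104",0,"2005-07-04"
"P00105",0,"2006-04-16"
"P00106",1,"2008-01-05"
"P00107",0,"2013-04-19"
"P00108",1,"2005-11-05"
"P00109",1,"2008-10-15"
"P00110",0,"2011-12-27"
"P00111",1,"2013-07-23"
"P00112",0,"2009-07-14"
"P00113",0,"2007-12-03"
"P00114",0,"2012-01-03"
"P00115",0,"2007-04-18"
"P00116",0,"2007-10-16"
"P00117",0,"2006-09-15"
"P00118",0,"2013-07-04"
"P00119",0,"2006-10-13"
"P00120",0,"2013-02-25"
"P00121",0,"2011-05-16"
"P00122",0,"2008-10-27"
"P00123",0,"2006-10-06"
"P00124",1,"2005-10-23"
"P00125",1,"2005-04-14"
"P00126",0,"2014-04-06"
"P00127",0,"2012-09-30"
"P00128",0,"2006-04-22"
"P00129",0,"2010-05-21"
"P00130",0,"2011-08-18"
"P00131",0,"2005-06-26"
"P00132",0,"2013-12-20"
"P00133",1,"2010-03-15"
"P00134",0,"2006-09-08"
"P00135",0,"2002-09-17"
"P00136",1,"2010-02-04"
"P00137",1,"2003-06-30"
"P00138",0,"2007-05-08"
"P00139",1,"2002-12-15"
"P00140",0,"2010-05-07"
"P00141",1,"2005-07-19"
"P00142",0,"2011-04-07"
"P00143",1,"2009-12-06"
"P00144",0,"2013-10-26"
"P00145",0,"2010-04-21"
"P00146",1,"2006-09-23"
"P00147",0,"2012-01-12"
"P00148",0,"2007-05-29"
"P00149",0,"2013-08-10"
"P00150",1,"2012-09-02"
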