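id,country,sex,birth_date,death_date,last_seen_date,birth_year,death_year,age_years,age_days,scheme
synthetic_sample-00001,synthetic_sample,F,1871-07-21,1976-12-20,,,,,,FULLY_OBSERVED
synthetic_sample-00002,synthetic_sample,F,1906-11-28,2012-04-28,,,,,,FULLY_OBSERVED
synthetic_sample-00003,synthetic_sample,M,1886-08-18,1993-04-24,,,,,,FULLY_OBSERVED
synthetic_sample-00004,synthetic_sample,F,1901-01-15,2006-04-28,,,,,,FULLY_OBSERVED
synthetic_sample-00005,synthetic_sample,F,1910-10-01,2016-08-16,,,,,,FULLY_OBSERVED
synthetic_sample-00006,synthetic_sample,F,1903-03-08,2010-03-12,,,,,,FULLY_OBSERVED
synthetic_sample-00007,synthetic_sample,F,1898-09-27,,2005-10-03,,,,,RIGHT_CENSORED
synthetic_sample-00008,synthetic_sample,F,1880-07-04,1989-04-14,,,,,,FULLY_OBSERVED
synthetic_sample-00009,synthetic_sample,F,1885-12-22,1991-02-19,,,,,,FULLY_OBSERVED
synthetic_sample-00010,synthetic_sample,F,1898-07-28,,2003-10-09,,,,,RIGHT_CENSORED
synthetic_sample-00011,synthetic_sample,F,1883-04-16,1988-10-09,,,,,,FULLY_OBSERVED
synthetic_sample-00012,synthetic_sample,F,1903-09-02,2009-10-02,,,,,,FULLY_OBSERVED
synthetic_sample-00013,synthetic_sample,F,1895-03-23,,2000-04-01,,,,,RIGHT_CENSORED
synthetic_sample-00014,synthetic_sample,F,1895-07-13,2000-10-24,,,,,,FULLY_OBSERVED
synthetic_sample-00015,synthetic_sample,F,1901-04-05,2008-01-30,,,,,,FULLY_OBSERVED
synthetic_sample-00016,synthetic_sample,F,1890-10-28,,1996-08-07,,,,,RIGHT_CENSORED
synthetic_sample-00017,synthetic_sample,F,1870-02-25,,1975-09-25,,,,,RIGHT_CENSORED
synthetic_sample-00018,synthetic_sample,F,1880-01-24,1985-02-07,,,,,,FULLY_OBSERVED
synthetic_sample-00019,synthetic_sample,F,1904-03-31,2010-12-05,,,,,,FULLY_OBSERVED
synthetic_sample-00020,synthetic_sample,F,1910-10-21,2017-09-11,,,,,,FULLY_OBSERVED
synthetic_sample-00021,synthetic_sample,F,1886-01-28,,1992-01-06,,,,,RIGHT_CENSORED
synthetic_sample-00022,synthetic_sample,F,1897-08-15,2004-10-21,,,,,,FULLY_OBSERVED
synthetic_sample-00023,synthetic_sample,F,,,,1893,2000,106,355,INTERVAL_CENSORED_YEARS
synthetic_sample-00024,synthetic_sample,F,1889-02-02,1995-01-04,,,,,,FULLY_OBSERVED
synthetic_sample-00025,synthetic_sample,F,1897-05-29,2004-11-22,,,,,,FULLY_OBSERVED
synthetic_sample-00026,synthetic_sample,F,1889-11-26,,1995-01-06,,,,,RIGHT_CENSORED
synthetic_sample-00027,synthetic_sample,F,1912-11-03,,2019-04-29,,,,,RIGHT_CENSORED
synthetic_sample-00028,synthetic_sample,F,1889-03-03,,1994-03-04,,,,,RIGHT_CENSORED
synthetic_sample-00029,synthetic_sample,F,1892-06-27,,1998-01-28,,,,,RIGHT_CENSORED
synthetic_sample-00030,synthetic_sample,F,1911-04-06,2018-03-10,,,,,,FULLY_OBSERVED
synthetic_sample-00031,synthetic_sample,F,1873-12-11,1980-02-18,,,,,,FULLY_OBSERVED
synthetic_sample-00032,synthetic_sample,M,,,,1876,1984,108,235,INTERVAL_CENSORED_YEARS
synthetic_sample-00033,synthetic_sample,F,1885-10-21,,1991-03-12,,,,,RIGHT_CENSORED
synthetic_sample-00034,synthetic_sample,F,1889-02-14,1994-09-08,,,,,,FULLY_OBSERVED
synthetic_sample-00035,synthetic_sample,F,1872-09-14,1985-09-07,,,,,,FULLY_OBSERVED
synthetic_sample-00036,synthetic_sample,M,1894-01-06,1999-03-27,,,,,,FULLY_OBSERVED
synthetic_sample-00037,synthetic_sample,F,1903-07-27,2008-09-20,,,,,,FULLY_OBSERVED
synthetic_sample-00038,synthetic_sample,F,1894-10-24,2000-06-11,,,,,,FULLY_OBSERVED
synthetic_sample-00039,synthetic_sample,F,1895-12-13,2001-12-26,,,,,,FULLY_OBSERVED
synthetic_sample-00040,synthetic_sample,F,1872-12-30,,1978-01-11,,,,,RIGHT_CENSORED
synthetic_sample-00041,synthetic_sample,F,1894-06-13,1999-06-28,,,,,,FULLY_OBSERVED
synthetic_sample-00042,synthetic_sample,F,1870-01-06,,1976-12-09,,,,,RIGHT_CENSORED
synthetic_sample-00043,synthetic_sample,F,,,,1875,1980,105,72,INTERVAL_CENSORED_YEARS
synthetic_sample-00044,synthetic_sample,F,1889-06-13,1997-11-05,,,,,,FULLY_OBSERVED
synthetic_sample-00045,synthetic_sample,F,1878-10-06,1986-10-15,,,,,,FULLY_OBSERVED
synthetic_sample-00046,synthetic_sample,F,,,,1884,1990,106,39,INTERVAL_CENSORED_YEARS
synthetic_sample-00047,synthetic_sample,F,,,,1882,1989,106,271,INTERVAL_CENSORED_YEARS
synthetic_sample-00048,synthetic_sample,F,1885-02-03,1990-03-13,,,,,,FULLY_OBSERVED
synthetic_sample-00049,synthetic_sample,F,,,,1912,2017,105,67,INTERVAL_CENSORED_YEARS
synthetic_sample-00050,synthetic_sample,M,,,,1903,2009,105,352,INTERVAL_CENSORED_YEARS
synthetic_sample-00051,synthetic_sample,M,1874-11-14,1989-08-31,,,,,,FULLY_OBSERVED
synthetic_sample-00052,synthetic_sample,F,1885-05-08,1992-09-09,,,,,,FULLY_OBSERVED
synthetic_sample-00053,synthetic_sample,F,1875-02-11,1980-02-24,,,,,,FULLY_OBSERVED
synthetic_sample-00054,synthetic_sample,F,,,,1872,1978,105,266,INTERVAL_CENSORED_YEARS
synthetic_sample-00055,synthetic_sample,F,,,,1894,1999,105,57,INTERVAL_CENSORED_YEARS
synthetic_sample-00056,synthetic_sample,F,1902-12-29,2009-09-28,,,,,,FULLY_OBSERVED
synthetic_sample-00057,synthetic_sample,F,1880-07-12,1986-05-29,,,,,,FULLY_OBSERVED
synthetic_sample-00058,synthetic_sample,F,1888-04-05,1993-12-09,,,,,,FULLY_OBSERVED
synthetic_sample-00059,synthetic_sample,F,1899-07-30,2004-09-14,,,,,,FULLY_OBSERVED
synthetic_sample-00060,synthetic_sample,F,,,,1894,1999,105,136,INTERVAL_CENSORED_YEARS
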